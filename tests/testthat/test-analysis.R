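# Superposition, RMSD series, pose clustering, H-bonds, distance tables.

random_structure <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 4), ncol = 3)
}

rigid_move <- function(x, th = 0.7, axis = c(0, 0, 1), shift = c(3, -2, 5)) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  x %*% t(R) + matrix(shift, nrow(x), 3, byrow = TRUE)
}

test_that("superposition of identical and rigidly moved structures is exact", {
  x <- random_structure(20, 1)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-12)
  y <- rigid_move(x)
  fit <- kabsch_superpose(y, x)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("superposition RMSD matches an orientation-search oracle", {
  for (seed in 1:3) {
    a <- random_structure(12, seed)
    b <- random_structure(12, seed + 50)
    got <- kabsch_superpose(a, b)$rmsd
    ref <- oracle_min_rmsd(a, b)
    expect_equal(got, ref, tolerance = 1e-4)
    expect_lte(got, ref + 1e-6) # least squares can never be beaten
  }
})

test_that("collinear selections are rejected", {
  line <- cbind(1:5, 0, 0) * 1.0
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("the RMSD time series is zero on itself and honours exclusions", {
  tr <- short_toy_trajectory()
  rs <- rmsd_timeseries(tr)
  expect_equal(rs$rmsd[1], 0, tolerance = 1e-12)
  expect_true(all(rs$rmsd >= 0))
  # excluding all but a few residues equals a direct superposition
  keep <- protein_residues(tr$topology)[1:4]
  excl <- setdiff(protein_residues(tr$topology), keep)
  rs2 <- rmsd_timeseries(tr, exclude_residues = excl)
  sel <- calpha_indices(tr$topology, residues = keep)
  direct <- kabsch_superpose(get_frame(tr, 5), get_frame(tr, 1), sel)$rmsd
  expect_equal(rs2$rmsd[5], direct, tolerance = 1e-12)
  expect_error(rmsd_timeseries(tr, exclude_residues = protein_residues(tr$topology)),
               "empty selection")
})

test_that("excluding a mobile loop can only lower the RMSD", {
  # constructed trajectory where residues of one helix move and the rest don't
  ts <- toy_system_small()
  topo <- ts$topology
  loop_res <- 1:10 # chain A
  loop_atoms <- which(topo$atoms$resid %in% loop_res)
  nfr <- 6
  frames <- array(0, dim = c(n_atoms(topo), 3, nfr))
  set.seed(31)
  for (f in seq_len(nfr)) {
    x <- ts$coordinates
    x[loop_atoms, ] <- x[loop_atoms, ] + matrix(rnorm(3, sd = 1.5 * (f - 1)),
                                                length(loop_atoms), 3,
                                                byrow = TRUE)
    frames[, , f] <- x
  }
  tr <- structure(list(topology = topo, frames = frames,
                       steps = 0:(nfr - 1), times = as.numeric(0:(nfr - 1)),
                       replica = rep(1L, nfr)),
                  class = "mmcg_trajectory")
  full <- rmsd_timeseries(tr)
  part <- rmsd_timeseries(tr, exclude_residues = loop_res)
  expect_true(all(part$rmsd <= full$rmsd + 1e-9))
})

test_that("ligand pose distance is the plain coordinate RMSD over ligand atoms", {
  ts <- toy_system_small()
  x <- ts$coordinates
  expect_equal(ligand_pose_distance(x, x, ts$topology), 0)
  y <- x
  y[ts$topology$ligand, 1] <- y[ts$topology$ligand, 1] + 2
  expect_equal(ligand_pose_distance(x, y, ts$topology), 2.0, tolerance = 1e-12)
  # hand formula on a random perturbation
  set.seed(4)
  z <- x
  z[ts$topology$ligand, ] <- z[ts$topology$ligand, ] +
    matrix(rnorm(3 * length(ts$topology$ligand), sd = 0.7), ncol = 3)
  lig <- ts$topology$ligand
  byhand <- sqrt(mean(rowSums((x[lig, ] - z[lig, ])^2)))
  expect_equal(ligand_pose_distance(x, z, ts$topology), byhand)
})

test_that("greedy clustering reproduces the worked 1-D example", {
  # four poses on a line at 0, 0.5, 0.9, 5.0 with a 1 A cutoff
  pos <- c(0, 0.5, 0.9, 5.0)
  D <- abs(outer(pos, pos, "-"))
  cl <- daura_cluster(D, cutoff = 1.0)
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(cl$clusters$center_frame[1], 1) # tie broken by lowest index
  expect_equal(sort(cl$members[[1]]), 1:3)
  expect_equal(cl$clusters$population, c(0.75, 0.25))
})

test_that("clustering is exhaustive, disjoint and matches the brute-force oracle", {
  set.seed(77)
  for (rep in 1:3) {
    n <- 60
    pts <- matrix(rnorm(2 * n, sd = 1.2), ncol = 2)
    D <- as.matrix(dist(pts))
    cl <- daura_cluster(D, cutoff = 1.0)
    all_members <- sort(unlist(cl$members))
    expect_equal(all_members, 1:n)
    expect_equal(sum(cl$clusters$population), 1, tolerance = 1e-9)
    ref <- oracle_daura(D, 1.0)
    expect_equal(length(cl$members), length(ref))
    for (k in seq_along(ref)) {
      expect_equal(cl$clusters$center_frame[k], ref[[k]]$center)
      expect_equal(sort(cl$members[[k]]), sort(ref[[k]]$members))
    }
  }
})

test_that("identical frames collapse to one cluster with population 1", {
  ts <- toy_system_small()
  tr <- make_reference_trajectory(ts$topology, ts$coordinates, "static",
                                  n_frames = 12)
  cl <- daura_cluster(tr)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$population, 1)
  expect_equal(central_structure(cl, tr, 1), get_frame(tr, 1),
               ignore_attr = TRUE)
})

test_that("central structures are the stored cluster centres", {
  pos <- c(0, 0.5, 0.9, 5.0)
  D <- abs(outer(pos, pos, "-"))
  cl <- daura_cluster(D, cutoff = 1.0)
  ts <- toy_system_small()
  tr <- make_reference_trajectory(ts$topology, ts$coordinates, "static",
                                  n_frames = 4)
  cs <- central_structure(cl, tr, 1)
  expect_equal(attr(cs, "frame"), 1L)
  expect_error(central_structure(cl, tr, 9), "out of range")
})

test_that("hydrogen-bond geometry follows the textbook cases", {
  atoms <- data.frame(serial = 1:3, name = c("N1", "HN1", "S1"),
                      element = c("N", "H", "S"), resid = 1L,
                      resname = "LIG", chain = "L")
  topo <- make_topology(atoms)
  nfr <- 1
  mk_traj <- function(x) {
    structure(list(topology = topo, frames = array(x, dim = c(3, 3, 1)),
                   steps = 0L, times = 0, replica = 1L),
              class = "mmcg_trajectory")
  }
  triples <- data.frame(donor = 1L, hydrogen = 2L, acceptor = 3L)
  # collinear N-H...S at 3.0 A: angle 180, bonded
  x1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  hb1 <- hbond_series(mk_traj(x1), triples)
  expect_equal(hb1$distance, 3.0)
  expect_equal(hb1$angle, 180)
  expect_true(hb1$hbond)
  # acceptor at right angles: ~71.6 deg -> not an H-bond
  x2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 3, 0))
  hb2 <- hbond_series(mk_traj(x2), triples)
  expect_equal(hb2$angle, acos(1 / sqrt(10)) * 180 / pi, tolerance = 1e-6)
  expect_equal(round(hb2$angle, 1), 71.6)
  expect_false(hb2$hbond)
  # degenerate criteria: zero distance cutoff switches everything off
  hb3 <- hbond_series(mk_traj(x1), triples, max_distance = 0)
  expect_false(any(hb3$hbond))
  # distances unaffected by rigid motion
  hb4 <- hbond_series(mk_traj(rigid_move(x1)), triples)
  expect_equal(hb4$distance, hb1$distance, tolerance = 1e-10)
  expect_equal(hb4$angle, hb1$angle, tolerance = 1e-8)
})

test_that("hbond histograms count distances per labeled pair", {
  ts <- toy_system_small()
  tr <- make_reference_trajectory(ts$topology, ts$coordinates, "random_walk",
                                  n_frames = 30, sigma = 0.2, seed = 3)
  lig <- ts$topology$ligand
  a <- ts$topology$atoms
  don <- lig[a$name[lig] == "N1"]
  h <- lig[a$name[lig] == "HN1"]
  acc <- ts$topology$water[a$element[ts$topology$water] == "O"][1]
  ser <- hbond_series(tr, data.frame(donor = don, hydrogen = h, acceptor = acc))
  hist <- hbond_histogram(ser, breaks = seq(0, 30, 0.5))
  expect_equal(sum(hist$count), nrow(ser))
})

test_that("distance tables compute atom, ring-centroid and side-chain distances", {
  # ring of 6 atoms on a unit hexagon vs a 4 A shifted copy of itself
  ring1 <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  ring2 <- sweep(ring1, 2, c(0, 0, -4))
  atoms <- data.frame(serial = 1:12,
                      name = paste0("C", c(1:6, 1:6)),
                      element = "C",
                      resid = rep(1:2, each = 6),
                      resname = "LIG", chain = "L")
  topo <- make_topology(atoms)
  frame <- rbind(ring1, ring2)
  spec <- list(
    list(label = "Ring1 - Ring2", a = 1:6, b = 7:12),
    list(label = "C1 - C1'", a = 1, b = 7),
    list(label = "sel - sel", a = list(resid = 1, name = "C3"),
         b = list(resid = 2, name = "C3"))
  )
  tab <- distance_table(frame, topo, spec)
  expect_equal(tab$distance[tab$label == "Ring1 - Ring2"], 4.0)
  expect_equal(tab$distance[tab$label == "C1 - C1'"], 4.0)
  expect_equal(tab$distance[tab$label == "sel - sel"], 4.0)
  expect_equal(attr(tab, "convention"), "centroid")
  # independent hand-coded distances on an arbitrary frame
  set.seed(9)
  frame2 <- frame + matrix(rnorm(36, sd = 0.5), ncol = 3)
  tab2 <- distance_table(frame2, topo, spec)
  byhand <- sqrt(sum((colMeans(frame2[1:6, ]) - colMeans(frame2[7:12, ]))^2))
  expect_equal(tab2$distance[1], byhand)
  expect_error(distance_table(frame, topo,
                              list(list(label = "x", a = list(name = "ZZ"), b = 1))),
               "no atoms")
})

test_that("replica joining concatenates frames and preserves ids", {
  sys <- prepared_toy_system()
  p <- make_integrator_params(seed = 12, n_steps = 400, output_stride = 100)
  trs <- run_replicas(sys, p, n_replicas = 2)
  expect_false(identical(trs[[1]]$frames, trs[[2]]$frames))
  joined <- join_replicas(trs)
  expect_equal(n_frames(joined), 10)
  expect_equal(unique(joined$replica), c(1L, 2L))
  # joining with a single trajectory is the identity
  expect_equal(n_frames(join_replicas(trs[1])), 5)
  # topology mismatch is an error
  other <- trs[[2]]
  other$topology <- make_topology(data.frame(serial = 1, name = "CA",
                                             element = "C", resid = 1,
                                             resname = "ALA", chain = "A"))
  other$frames <- array(0, dim = c(1, 3, 2))
  expect_error(join_replicas(list(trs[[1]], other)), "mismatch")
})

test_that("cluster populations on joined replicas match a global brute-force run", {
  ts <- toy_system_small()
  tr1 <- make_reference_trajectory(ts$topology, ts$coordinates,
                                   "two_pose_switch", n_frames = 40,
                                   split = 0.5)
  tr2 <- make_reference_trajectory(ts$topology, ts$coordinates,
                                   "two_pose_switch", n_frames = 20,
                                   split = 1.0)
  tr2$replica <- rep(2L, 20)
  joined <- join_replicas(list(tr1, tr2))
  cl <- daura_cluster(joined, cutoff = 1.0)
  D <- mmcg:::pose_distance_matrix(joined)
  ref <- oracle_daura(D, 1.0)
  expect_equal(cl$clusters$size,
               vapply(ref, function(c) length(c$members), integer(1)))
  expect_equal(cl$clusters$population, c(40 / 60, 20 / 60))
})
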