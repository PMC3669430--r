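# Energy/force correctness of the MM, Go and cutoff machinery.

two_atom_topology <- function() {
  make_topology(data.frame(serial = 1:2, name = "CA", element = "C",
                           resid = 1:2, resname = "ALA", chain = "A"),
                bonds = cbind(1L, 2L))
}

# finite-difference gradient check against an energy function
fd_check <- function(energy_fn, coords, forces, n_comp = 6, h = 1e-5,
                     tol = 1e-5, seed = 1) {
  set.seed(seed)
  picks <- cbind(sample(nrow(coords), n_comp, replace = TRUE),
                 sample(3, n_comp, replace = TRUE))
  for (r in seq_len(n_comp)) {
    i <- picks[r, 1]; k <- picks[r, 2]
    xp <- coords; xp[i, k] <- xp[i, k] + h
    xm <- coords; xm[i, k] <- xm[i, k] - h
    fd <- -(energy_fn(xp) - energy_fn(xm)) / (2 * h)
    err <- abs(fd - forces[i, k]) / max(1, abs(forces[i, k]))
    expect_lt(err, tol)
  }
}

test_that("harmonic bond energies follow the closed form", {
  topo <- two_atom_topology()
  params <- toy_parameters()
  params$bond_types[["CA:CA"]] <- list(k = 100, r0 = 1.0)
  # at r = r0: zero energy, zero force
  er0 <- mm_bonded_energy_forces(topo, rbind(c(0, 0, 0), c(1, 0, 0)), params)
  expect_equal(er0$terms[["bond"]], 0)
  expect_equal(max(abs(er0$forces)), 0)
  # k = 100, r0 = 1, r = 1.5 -> E = 0.5 * 100 * 0.25 = 12.5
  er <- mm_bonded_energy_forces(topo, rbind(c(0, 0, 0), c(1.5, 0, 0)), params)
  expect_equal(er$terms[["bond"]], 12.5)
  expect_error(
    mm_bonded_energy_forces(topo, rbind(c(0, 0, 0), c(0, 0, 0)), params),
    "zero-length"
  )
})

test_that("bonded forces match finite differences on random conformations", {
  ts <- toy_system_small()
  params <- toy_parameters()
  lig <- ts$topology$ligand
  lig_atoms <- ts$topology$atoms[lig, ]
  lig_atoms$serial <- seq_along(lig)
  lig_topo <- make_topology(
    lig_atoms,
    bonds = {
      b <- ts$topology$bonds
      b <- b[b[, 1] %in% lig & b[, 2] %in% lig, , drop = FALSE]
      cbind(match(b[, 1], lig), match(b[, 2], lig))
    }
  )
  set.seed(7)
  for (rep in 1:3) {
    x <- ts$coordinates[lig, ] + matrix(rnorm(3 * length(lig), sd = 0.15),
                                        ncol = 3)
    er <- mm_bonded_energy_forces(lig_topo, x, params)
    fd_check(function(xx) mm_bonded_energy_forces(lig_topo, xx, params)$total,
             x, er$forces, seed = rep)
  }
})

test_that("LJ pair energies hit the textbook landmarks", {
  topo <- make_topology(data.frame(serial = 1:2, name = "CA", element = "C",
                                   resid = 1:2, resname = "ALA", chain = "A"))
  params <- toy_parameters()
  sig <- params$atom_types$CA$sigma
  eps <- params$atom_types$CA$epsilon
  # at r = sigma the unshifted LJ is zero: only the shift constant remains
  er <- mm_nonbonded_energy_forces(topo, rbind(c(0, 0, 0), c(sig, 0, 0)), params)
  shift_const <- -4 * eps * ((sig / 16)^12 - (sig / 16)^6)
  expect_equal(er$terms[["lj"]], shift_const, tolerance = 1e-12)
  # at the minimum with the shift disabled: exactly -eps
  er2 <- mm_nonbonded_energy_forces(topo,
                                    rbind(c(0, 0, 0), c(2^(1 / 6) * sig, 0, 0)),
                                    params, shift = FALSE)
  expect_equal(er2$terms[["lj"]], -eps, tolerance = 1e-12)
  expect_equal(max(abs(er2$forces)), 0, tolerance = 1e-10)
  expect_error(
    mm_nonbonded_energy_forces(topo, rbind(c(0, 0, 0), c(1e-8, 0, 0)), params),
    "overlapping"
  )
})

test_that("nonbonded energies/forces equal a direct all-pairs sum", {
  # 20 random charged LJ particles vs an independent R-level sum
  set.seed(42)
  n <- 20L
  x <- matrix(runif(3 * n, 0, 10), ncol = 3)
  q <- round(runif(n, -0.5, 0.5), 3)
  sig <- runif(n, 3, 4)
  eps <- runif(n, 0.1, 0.7)
  r_cut <- 6.0
  sys <- mmcg:::cpp_sys_skeleton(n, rep(12, n))
  sys$charge <- q; sys$sigma <- sig; sys$eps <- eps; sys$r_cut <- r_cut
  got <- mmcg:::cpp_energy_forces(sys, x)

  ke <- 1389.35458
  e_ref <- 0
  f_ref <- matrix(0, n, 3)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- x[i, ] - x[j, ]
      r <- sqrt(sum(d^2))
      if (r >= r_cut) next
      sij <- (sig[i] + sig[j]) / 2
      eij <- sqrt(eps[i] * eps[j])
      sr6 <- (sij / r)^6
      cr6 <- (sij / r_cut)^6
      e_lj <- 4 * eij * (sr6^2 - sr6) - 4 * eij * (cr6^2 - cr6)
      # Coulomb uses shifted-force truncation (energy and force zero at r_cut)
      e_c <- ke * q[i] * q[j] * (1 / r - 1 / r_cut + (r - r_cut) / r_cut^2)
      e_ref <- e_ref + e_lj + e_c
      dEdr <- -24 * eij * (2 * sr6^2 - sr6) / r +
        ke * q[i] * q[j] * (-1 / r^2 + 1 / r_cut^2)
      f_ref[i, ] <- f_ref[i, ] - dEdr * d / r
      f_ref[j, ] <- f_ref[j, ] + dEdr * d / r
    }
  }
  expect_equal(got$terms[["lj"]] + got$terms[["coulomb"]], e_ref,
               tolerance = 1e-9)
  expect_equal(got$forces, f_ref, tolerance = 1e-9)
})

test_that("pair energies are continuous (zero) at the cutoff", {
  topo <- make_topology(data.frame(serial = 1:2, name = "CA", element = "C",
                                   resid = 1:2, resname = "ALA", chain = "A"))
  params <- toy_parameters()
  for (delta in c(1e-3, 1e-5, 1e-7)) {
    er <- mm_nonbonded_energy_forces(
      topo, rbind(c(0, 0, 0), c(16 - delta, 0, 0)), params)
    expect_lt(abs(er$terms[["lj"]] + er$terms[["coulomb"]]), 1e-4)
  }
})

test_that("an ideal helix gives 9 chain bonds at ~3.8 A and an extended chain no contacts", {
  n <- 10L
  helix <- t(sapply(0:(n - 1), function(i) {
    c(2.3 * cos(100 * pi / 180 * i), 2.3 * sin(100 * pi / 180 * i), 1.5 * i)
  }))
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                      resid = seq_len(n), resname = "ALA", chain = "A")
  topo <- make_topology(atoms)
  reg <- structure(setNames(rep("CG", n), seq_len(n)), class = "mmcg_regions",
                   interface_cutoff = 6)
  go <- build_go_model(topo, helix, reg)
  expect_equal(nrow(go$chain_bonds), 9)
  expect_equal(go$chain_bonds$r_nat, rep(3.83, 9), tolerance = 1e-2)

  extended <- cbind(seq(0, by = 10, length.out = n), 0, 0)
  go2 <- build_go_model(topo, extended, reg, r_cut = 1e6)
  expect_equal(nrow(go2$contacts), 0)
})

test_that("the toy-bundle contact map equals a brute-force heavy-atom scan", {
  ts <- toy_system_small()
  reg <- toy_regions_small()
  go <- build_go_model(ts$topology, ts$coordinates, reg)
  bead_res <- sort(residues_in_region(reg, c("CG", "I")))
  a <- ts$topology$atoms
  heavy <- !a$is_hydrogen
  oracle <- list()
  for (p in seq_along(bead_res)) {
    for (q in seq_along(bead_res)) {
      if (q <= p) next
      ri <- bead_res[p]; rj <- bead_res[q]
      ci <- a$chain[which(a$resid == ri)][1]
      cj <- a$chain[which(a$resid == rj)][1]
      if (ci == cj && abs(rj - ri) < 3) next
      ai <- which(a$resid == ri & heavy)
      aj <- which(a$resid == rj & heavy)
      dmin <- Inf
      for (i in ai) for (j in aj) {
        dmin <- min(dmin, sqrt(sum((ts$coordinates[i, ] - ts$coordinates[j, ])^2)))
      }
      if (dmin <= 4.5) oracle[[length(oracle) + 1]] <- c(ri, rj)
    }
  }
  oracle <- do.call(rbind, oracle)
  got <- as.matrix(go$contacts[, c("i", "j")])
  expect_equal(got[order(got[, 1], got[, 2]), ],
               oracle[order(oracle[, 1], oracle[, 2]), ],
               ignore_attr = TRUE)
  expect_gt(nrow(go$contacts), 0)
})

test_that("Go energies are minimal at the native structure", {
  ts <- toy_system_small()
  reg <- toy_regions_small()
  go <- build_go_model(ts$topology, ts$coordinates, reg)
  er <- go_energy_forces(go, go$native_ca)
  # every contact at its native distance: energy -eps per contact (up to the
  # tiny cutoff shift), chain bonds exactly zero
  expect_equal(er$terms[["go_bond"]], 0, tolerance = 1e-10)
  expect_equal(er$terms[["go_contact"]], -go$eps_go * nrow(go$contacts),
               tolerance = 1e-3 * go$eps_go * nrow(go$contacts))
  # stationary point of chain + contact terms: forces from those terms only
  go_iso <- go
  er_shiftless <- go_energy_forces(go_iso, go$native_ca, shift = FALSE)
  expect_equal(er_shiftless$terms[["go_contact"]],
               -go$eps_go * nrow(go$contacts), tolerance = 1e-12)
})

test_that("a single native contact at r_nat has zero force", {
  atoms <- data.frame(serial = 1:2, name = "CA", element = "C",
                      resid = c(1L, 10L), resname = "ALA", chain = c("A", "B"))
  topo <- make_topology(atoms)
  coords <- rbind(c(0, 0, 0), c(4.2, 0, 0))
  reg <- structure(setNames(c("CG", "CG"), c(1, 10)), class = "mmcg_regions")
  go <- build_go_model(topo, coords, reg, eps_go = 2.5)
  expect_equal(nrow(go$contacts), 1)
  er <- go_energy_forces(go, coords, shift = FALSE)
  expect_equal(er$terms[["go_contact"]], -2.5, tolerance = 1e-12)
  expect_equal(max(abs(er$forces)), 0, tolerance = 1e-9)
})

test_that("Go forces match finite differences on random bead configurations", {
  ts <- toy_system_small()
  go <- build_go_model(ts$topology, ts$coordinates, toy_regions_small())
  set.seed(11)
  x <- go$native_ca + matrix(rnorm(length(go$native_ca), sd = 0.3), ncol = 3)
  er <- go_energy_forces(go, x)
  fd_check(function(xx) go_energy_forces(go, xx)$total, x, er$forces, seed = 3)
})

test_that("missing C-alpha in the native structure names the residue", {
  atoms <- data.frame(serial = 1:2, name = c("CA", "CB"), element = "C",
                      resid = c(1L, 2L), resname = "ALA", chain = "A")
  topo <- make_topology(atoms)
  reg <- structure(setNames(c("CG", "CG"), c(1, 2)), class = "mmcg_regions")
  expect_error(build_go_model(topo, matrix(0:5, 2, 3), reg), "residue 2")
})

test_that("total energy is the sum of its terms and forces are exact gradients", {
  sys <- prepared_toy_system()
  er <- total_energy_forces(sys)
  expect_equal(er$total, sum(er$terms), tolerance = 1e-9)
  set.seed(5)
  x <- sys$coordinates + matrix(rnorm(length(sys$coordinates), sd = 0.03),
                                ncol = 3)
  er2 <- total_energy_forces(sys, x)
  fd_check(function(xx) total_energy_forces(sys, xx)$total, x, er2$forces,
           n_comp = 8, seed = 9)
})

test_that("term gating: a water-only system has only water LJ/Coulomb and wall energy", {
  ts <- toy_system_small()
  reg <- toy_regions_small()
  sys <- build_system(ts$topology, ts$coordinates, reg, toy_parameters(),
                      walls = ts$wall_hints, enable = c("nonbonded", "walls"))
  er <- total_energy_forces(sys)
  expect_equal(er$terms[["bond"]], 0)
  expect_equal(er$terms[["angle"]], 0)
  expect_equal(er$terms[["go_contact"]], 0)
  expect_equal(er$total,
               er$terms[["lj"]] + er$terms[["coulomb"]] +
                 er$terms[["go_rep"]] + er$terms[["wall"]])
})

test_that("internal energies are invariant under rigid motion; net force and torque vanish", {
  ts <- toy_system_small()
  reg <- toy_regions_small()
  sys <- build_system(ts$topology, ts$coordinates, reg, toy_parameters(),
                      walls = FALSE)
  x <- sys$coordinates
  er <- total_energy_forces(sys, x)
  # net force and net torque of internal terms are zero
  expect_lt(max(abs(colSums(er$forces))), 1e-8)
  tq <- colSums(cbind(
    x[, 2] * er$forces[, 3] - x[, 3] * er$forces[, 2],
    x[, 3] * er$forces[, 1] - x[, 1] * er$forces[, 3],
    x[, 1] * er$forces[, 2] - x[, 2] * er$forces[, 1]
  ))
  expect_lt(max(abs(tq)), 1e-6)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  x2 <- x %*% R + matrix(c(-4, 2, 9), nrow(x), 3, byrow = TRUE)
  er2 <- total_energy_forces(sys, x2)
  expect_equal(er2$total, er$total, tolerance = 1e-9)
})

test_that("the Verlet pair list reproduces the brute-force pair sum exactly", {
  sys <- prepared_toy_system()
  set.seed(13)
  for (rep in 1:3) {
    x <- sys$coordinates + matrix(rnorm(length(sys$coordinates), sd = 0.1),
                                  ncol = 3)
    a <- mmcg:::cpp_energy_forces(sys$cpp, x)
    b <- mmcg:::cpp_energy_forces_bruteforce(sys$cpp, x)
    expect_identical(a$terms, b$terms)
    expect_identical(a$forces, b$forces)
  }
})

test_that("energy reports serialize to delimited text", {
  sys <- prepared_toy_system()
  er <- total_energy_forces(sys)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_energy_report(er, f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(df$energy[df$term == "total"], er$total)
  td <- tidy(er)
  expect_equal(nrow(td), length(er$terms))
})
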