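# Shared fixtures, built once per test session and cached.

.toy_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.toy_cache[[key]])) .toy_cache[[key]] <- builder()
  .toy_cache[[key]]
}

toy_system_small <- function() {
  cached("toy_small", function() make_toy_system(seed = 1, n_waters = 20))
}

toy_regions_small <- function() {
  cached("reg_small", function() {
    ts <- toy_system_small()
    assign_regions(ts$topology, ts$coordinates, ts$mm_residues)
  })
}

prepared_toy_system <- function() {
  cached("sys_small", function() {
    ts <- toy_system_small()
    sys <- build_system(ts$topology, ts$coordinates, toy_regions_small(),
                        toy_parameters(), walls = ts$wall_hints)
    prepare_system(sys)
  })
}

short_toy_trajectory <- function() {
  cached("traj_small", function() {
    p <- make_integrator_params(seed = 42, n_steps = 1000, output_stride = 100)
    run_simulation(prepared_toy_system(), p)
  })
}

# a bare interaction-free system of n particles (for thermostat checks)
free_particle_system <- function(n, mass = 12.011) {
  structure(list(cpp = mmcg:::cpp_sys_skeleton(n, rep(mass, n)),
                 coordinates = matrix(0, n, 3),
                 topology = NULL, constraints = NULL),
            class = "mmcg_system")
}

# ---------------------------------------------------------------------------
# Independent oracles (deliberately written as plain loops, separate from the
# package's implementations).

# all-pairs heavy-atom region oracle
oracle_assign_regions <- function(topology, coords, mm_residues, cutoff) {
  prot <- protein_residues(topology)
  out <- setNames(rep("CG", length(prot)), prot)
  out[as.character(mm_residues)] <- "MM"
  a <- topology$atoms
  heavy <- !a$is_hydrogen
  special <- c(topology$ligand, topology$water)
  mm_atoms <- c(setdiff(which(a$resid %in% mm_residues & heavy), special),
                topology$ligand[heavy[topology$ligand]])
  for (r in setdiff(prot, mm_residues)) {
    idx <- which(a$resid == r & heavy)
    hit <- FALSE
    for (i in idx) {
      for (j in mm_atoms) {
        d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        if (d <= cutoff) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) out[as.character(r)] <- "I"
  }
  out
}

# greedy largest-neighborhood clustering oracle on a distance matrix
oracle_daura <- function(D, cutoff) {
  n <- nrow(D)
  left <- seq_len(n)
  clusters <- list()
  while (length(left) > 0) {
    best <- NULL; best_n <- -1
    for (i in left) {
      cnt <- 0
      for (j in left) if (D[i, j] <= cutoff) cnt <- cnt + 1
      if (cnt > best_n) { best <- i; best_n <- cnt }
    }
    mem <- left[D[best, left] <= cutoff]
    clusters[[length(clusters) + 1]] <- list(center = best, members = mem)
    left <- setdiff(left, mem)
  }
  ord <- order(-vapply(clusters, function(c) length(c$members), integer(1)),
               vapply(clusters, function(c) min(c$members), integer(1)))
  clusters[ord]
}

# orientation-search RMSD oracle: coarse quaternion grid + local refinement,
# never touching the SVD path
oracle_min_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) {
    R <- rot(q)
    sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
  }
  best_q <- NULL; best <- Inf
  grid <- as.matrix(expand.grid(w = seq(-1, 1, length.out = 5),
                                x = seq(-1, 1, length.out = 5),
                                y = seq(-1, 1, length.out = 5),
                                z = seq(-1, 1, length.out = 5)))
  grid <- grid[rowSums(grid^2) > 1e-6, ]
  for (r in seq_len(nrow(grid))) {
    v <- obj(grid[r, ])
    if (v < best) { best <- v; best_q <- grid[r, ] }
  }
  opt <- optim(best_q, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}
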