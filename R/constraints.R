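#' Build the SHAKE constraint set
#'
#' One distance constraint per bond containing at least one hydrogen, at the
#' bond's parameter length, plus fully rigid 3-site water: two O-H
#' constraints and one H-H constraint per molecule (the H-H distance follows
#' from the water geometry, `2 d_OH sin(angle/2)`).
#'
#' @param topology an `mmcg_topology`
#' @param parameters an `mmcg_parameters` set (bond lengths, water geometry)
#' @param rigid_water constrain water rigid (default TRUE); when FALSE water
#'   is left flexible and its bonds are handled as harmonic terms
#' @param tol relative distance tolerance enforced after every step
#' @param max_iterations SHAKE iteration cap
#' @return an `mmcg_constraints` object (data frame `i`, `j`, `d0` with
#'   attributes `tol`, `max_iterations`)
#' @export
build_constraints <- function(topology, parameters, rigid_water = TRUE,
                              tol = 1e-4, max_iterations = 500L) {
  a <- topology$atoms
  n <- n_atoms(topology)
  is_water <- seq_len(n) %in% topology$water
  ap <- NULL # lazy: only needed for non-water H bonds

  # every hydrogen must be reachable through a bond
  h_idx <- which(a$is_hydrogen)
  if (length(h_idx) > 0) {
    bonded <- unique(as.vector(topology$bonds))
    orphan <- setdiff(h_idx, bonded)
    if (length(orphan) > 0) {
      stop("hydrogen atom(s) with no bond: index ",
           paste(orphan, collapse = ", "))
    }
  }

  ci <- integer(0); cj <- integer(0); d0 <- numeric(0)
  w <- parameters$water
  bonds <- topology$bonds
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      if (is_water[i] && is_water[j]) {
        if (!rigid_water) next
        ci <- c(ci, i); cj <- c(cj, j); d0 <- c(d0, w$d_oh)
      } else if (a$is_hydrogen[i] || a$is_hydrogen[j]) {
        if (is.null(ap)) ap <- atom_params(topology, parameters)
        ent <- lookup_bond(parameters, ap$type[i], ap$type[j])
        ci <- c(ci, i); cj <- c(cj, j); d0 <- c(d0, ent$r0)
      }
    }
  }

  # H-H constraint closing each rigid water triangle
  if (rigid_water && length(topology$water) > 0) {
    d_hh <- 2 * w$d_oh * sin(w$angle * pi / 180 / 2)
    for (r in unique(a$resid[topology$water])) {
      idx <- atoms_of_residue(topology, r)
      h <- idx[a$is_hydrogen[idx]]
      if (length(h) == 2) {
        ci <- c(ci, h[1]); cj <- c(cj, h[2]); d0 <- c(d0, d_hh)
      }
    }
  }

  structure(data.frame(i = ci, j = cj, d0 = d0),
            tol = tol, max_iterations = as.integer(max_iterations),
            class = c("mmcg_constraints", "data.frame"))
}

n_constraints <- function(constraints) {
  if (is.null(constraints)) 0L else nrow(constraints)
}
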