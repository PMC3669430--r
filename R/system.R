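#' Assemble a simulation-ready hybrid MM/CG system
#'
#' Coarse-grains the structure according to the region assignment (CG
#' residues are reduced to their C-alpha bead carrying the full residue
#' mass; MM and I residues stay atomistic), attaches the MM force field to
#' the atomistic part, maps the Go model onto the beads, builds walls and
#' constraints, and packs everything for the compiled engine.
#'
#' Interface coupling: I-region atoms are evaluated by the MM force field
#' alongside the MM region; the I-region C-alphas additionally carry the
#' full Go bonded network (chain bonds and native contacts, to CG beads and
#' to each other), so both resolutions overlap across the interface as in
#' the parent multiscale scheme. A Go chain bond is dropped only where the
#' same C-alpha pair is already connected by an atomistic backbone bond.
#' Pure CG beads interact with atomistic particles only through a soft
#' `(sigma_rep/r)^12` repulsion, preventing overlap without mixing
#' resolutions; the repulsion skips sequence-local pairs (separation of 2
#' residues or less within a chain), whose geometry the bonded terms carry.
#'
#' @param topology native all-atom `mmcg_topology`
#' @param coordinates native coordinates, `n x 3`, Angstrom
#' @param regions `mmcg_regions` from [assign_regions()]
#' @param parameters `mmcg_parameters`
#' @param go_model optional `mmcg_go_model`; built from the native structure
#'   with default parameters when `NULL`
#' @param walls `TRUE` (build with defaults), `FALSE`/`NULL`, an
#'   `mmcg_walls` object, or a named list of [build_walls()] arguments
#' @param rigid_water constrain water (and H bonds) with SHAKE; `FALSE`
#'   leaves everything flexible (used e.g. for microcanonical checks)
#' @param enable character subset of
#'   `c("bonded", "nonbonded", "go", "walls")`: term groups evaluated by the
#'   engine (all by default)
#' @return an `mmcg_system`
#' @export
build_system <- function(topology, coordinates, regions, parameters,
                         go_model = NULL, walls = TRUE, rigid_water = TRUE,
                         enable = c("bonded", "nonbonded", "go", "walls")) {
  coordinates <- check_coords(topology, coordinates)
  enable <- match.arg(enable, several.ok = TRUE)
  if (is.null(go_model)) {
    go_model <- build_go_model(topology, coordinates, regions,
                               sigma_rep = parameters$options$sigma_rep,
                               r_cut = parameters$options$r_cut)
  }

  cg_res <- residues_in_region(regions, "CG")
  i_res <- residues_in_region(regions, "I")

  # ---- coarse-grain: CG residues keep only the C-alpha -------------------
  keep <- rep(TRUE, n_atoms(topology))
  bead_mass <- setNames(rep(NA_real_, length(cg_res)), cg_res)
  for (r in cg_res) {
    idx <- atoms_of_residue(topology, r)
    ca <- idx[topology$atoms$name[idx] == "CA"]
    if (length(ca) == 0) stop("missing C-alpha for CG residue ", r)
    keep[setdiff(idx, ca[1])] <- FALSE
    bead_mass[as.character(r)] <- sum(topology$atoms$mass[idx])
  }
  old2new <- cumsum(keep)
  old2new[!keep] <- NA_integer_

  atoms <- topology$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  cg_mask <- atoms$resid %in% cg_res
  atoms$mass[cg_mask] <- bead_mass[as.character(atoms$resid[cg_mask])]
  bonds <- topology$bonds
  if (nrow(bonds) > 0) {
    ok <- keep[bonds[, 1]] & keep[bonds[, 2]]
    bonds <- cbind(old2new[bonds[ok, 1]], old2new[bonds[ok, 2]])
    # bonds between two CG beads are replaced by Go chain bonds
    new_cg <- which(cg_mask)
    drop_go <- bonds[, 1] %in% new_cg & bonds[, 2] %in% new_cg
    bonds <- bonds[!drop_go, , drop = FALSE]
    # likewise CG-bead to atomistic backbone bonds: the chain coupling at
    # the region boundary is carried by the Go chain bond
    cross <- xor(bonds[, 1] %in% new_cg, bonds[, 2] %in% new_cg)
    bonds <- bonds[!cross, , drop = FALSE]
  }
  sim_top <- make_topology(atoms, bonds = bonds,
                           water_resnames = unique(atoms$resname[old2new[topology$water]]),
                           ligand_resnames = unique(atoms$resname[old2new[topology$ligand]]))
  sim_coords <- coordinates[keep, , drop = FALSE]

  ns <- n_atoms(sim_top)
  is_bead <- as.integer(sim_top$atoms$resid %in% cg_res)
  is_gonode <- as.integer(sim_top$atoms$resid %in% c(cg_res, i_res) &
                            sim_top$atoms$name == "CA")

  # ---- constraints + MM terms on the atomistic part ----------------------
  constraints <- if (rigid_water) {
    build_constraints(sim_top, parameters, rigid_water = TRUE)
  } else {
    structure(data.frame(i = integer(0), j = integer(0), d0 = numeric(0)),
              tol = 1e-4, max_iterations = 500L,
              class = c("mmcg_constraints", "data.frame"))
  }
  atom_rows <- which(is_bead == 0L)
  bt <- build_bonded_terms(sim_top, parameters,
                           constrained = as.matrix(constraints[, c("i", "j")]))

  sys <- cpp_sys_skeleton(ns, sim_top$atoms$mass)
  sys$is_bead <- is_bead
  sys$is_gonode <- is_gonode
  sys$is_h <- as.integer(sim_top$atoms$is_hydrogen)
  if ("bonded" %in% enable) {
    sys$bond_i <- bt$bonds$i; sys$bond_j <- bt$bonds$j
    sys$bond_k <- bt$bonds$k; sys$bond_r0 <- bt$bonds$r0
    sys$ang_i <- bt$angles$i; sys$ang_j <- bt$angles$j; sys$ang_k <- bt$angles$k
    sys$ang_kth <- bt$angles$kth; sys$ang_th0 <- bt$angles$th0
    sys$dih_i <- bt$dihedrals$i; sys$dih_j <- bt$dihedrals$j
    sys$dih_k <- bt$dihedrals$k; sys$dih_l <- bt$dihedrals$l
    sys$dih_kd <- bt$dihedrals$kd; sys$dih_n <- bt$dihedrals$n
    sys$dih_phase <- bt$dihedrals$phase
  }
  if ("nonbonded" %in% enable) {
    sys$charge <- bt$atom_params$charge * (1 - is_bead)
    sys$sigma <- pmax(bt$atom_params$sigma, 1e-3)
    sys$eps <- bt$atom_params$eps * (1 - is_bead)
    sys$excl_i <- c(bt$excl$i, bt$p14$i)
    sys$excl_j <- c(bt$excl$j, bt$p14$j)
    sys$p14_i <- bt$p14$i; sys$p14_j <- bt$p14$j
    sys$scale14_lj <- parameters$options$scale14_lj
    sys$scale14_coul <- parameters$options$scale14_coul
    sys$eps_rep <- parameters$options$eps_rep
  } else {
    sys$eps_rep <- 0.0
  }
  sys$sigma_rep <- go_model$sigma_rep
  sys$r_cut <- parameters$options$r_cut
  sys$shift <- parameters$options$shift

  # ---- Go terms on the beads (drop pure I-I pairs) -----------------------
  if ("go" %in% enable) {
    ca_sim <- setNames(
      vapply(go_model$beads$resid, function(r) {
        idx <- select_atoms(sim_top, resid = r, name = "CA")
        if (length(idx) == 0) stop("C-alpha of residue ", r,
                                   " lost during coarse-graining")
        idx[1]
      }, integer(1)),
      go_model$beads$resid
    )
    cb <- go_model$chain_bonds
    if (nrow(cb) > 0) {
      # drop a Go chain bond where the pair is already an atomistic bond
      bond_key <- paste(pmin(sim_top$bonds[, 1], sim_top$bonds[, 2]),
                        pmax(sim_top$bonds[, 1], sim_top$bonds[, 2]))
      ii <- unname(ca_sim[as.character(cb$i)])
      jj <- unname(ca_sim[as.character(cb$j)])
      dup <- paste(pmin(ii, jj), pmax(ii, jj)) %in% bond_key
      sys$gob_i <- ii[!dup]
      sys$gob_j <- jj[!dup]
      sys$gob_r0 <- cb$r_nat[!dup]
      sys$gob_k <- rep(go_model$k_chain, sum(!dup))
    }
    ct <- go_model$contacts
    if (nrow(ct) > 0) {
      sys$goc_i <- unname(ca_sim[as.character(ct$i)])
      sys$goc_j <- unname(ca_sim[as.character(ct$j)])
      sys$goc_r0 <- ct$r_nat
      sys$goc_eps <- rep(go_model$eps_go, nrow(ct))
    }
    # soft repulsion skips sequence-local neighbours of each CG bead and
    # every particle pair of native-contact residues (a contacting pair
    # interacts through its 12-10 well only, as in standard
    # structure-based models)
    skip_i <- integer(0); skip_j <- integer(0)
    for (b in which(is_bead == 1L)) {
      rb <- sim_top$atoms$resid[b]; chb <- sim_top$atoms$chain[b]
      near <- which(sim_top$atoms$chain == chb &
                      abs(sim_top$atoms$resid - rb) <= 2)
      near <- near[near != b]
      if (length(near) > 0) {
        skip_i <- c(skip_i, pmin(b, near))
        skip_j <- c(skip_j, pmax(b, near))
      }
    }
    if (nrow(go_model$contacts) > 0) {
      for (ci in seq_len(nrow(go_model$contacts))) {
        ai <- select_atoms(sim_top, resid = go_model$contacts$i[ci])
        aj <- select_atoms(sim_top, resid = go_model$contacts$j[ci])
        grid <- expand.grid(a = ai, b = aj)
        skip_i <- c(skip_i, pmin(grid$a, grid$b))
        skip_j <- c(skip_j, pmax(grid$a, grid$b))
      }
    }
    sys$skip_i <- skip_i; sys$skip_j <- skip_j
  }

  # ---- walls -------------------------------------------------------------
  wall_obj <- NULL
  if ("walls" %in% enable && !isFALSE(walls) && !is.null(walls)) {
    if (inherits(walls, "mmcg_walls")) {
      wall_obj <- walls
    } else if (isTRUE(walls)) {
      wall_obj <- build_walls(sim_top, sim_coords)
    } else if (is.list(walls)) {
      wall_obj <- do.call(build_walls,
                          c(list(topology = sim_top, coordinates = sim_coords),
                            walls))
    }
    if (!is.null(attr(wall_obj, "coordinates"))) {
      sim_coords <- attr(wall_obj, "coordinates")
    }
    sys$walls <- walls_cpp(wall_obj)
  }

  sys$con_i <- constraints$i; sys$con_j <- constraints$j
  sys$con_d0 <- constraints$d0
  sys$con_tol <- attr(constraints, "tol")
  sys$con_maxit <- attr(constraints, "max_iterations")

  structure(
    list(topology = sim_top, coordinates = sim_coords, regions = regions,
         parameters = parameters, go_model = go_model, walls = wall_obj,
         constraints = constraints, cpp = sys,
         native_topology = topology, native_map = which(keep)),
    class = "mmcg_system"
  )
}

#' @export
print.mmcg_system <- function(x, ...) {
  cat("mmcg hybrid system:", n_atoms(x$topology), "particles (",
      sum(x$cpp$is_bead), "CG beads ),", n_constraints(x$constraints),
      "constraints\n")
  print(x$regions)
  invisible(x)
}

#' Total energy and forces of a hybrid system
#'
#' Sums every enabled term group (MM bonded, MM nonbonded, Go, walls) with a
#' per-term breakdown. Forces are the exact analytic negative gradient of
#' the total energy.
#'
#' @param system an `mmcg_system`
#' @param coordinates optional coordinates (defaults to the system's)
#' @return an `mmcg_energy_report`
#' @export
total_energy_forces <- function(system, coordinates = NULL) {
  if (is.null(coordinates)) coordinates <- system$coordinates
  coordinates <- check_coords(system$topology, coordinates)
  energy_report(cpp_energy_forces(system$cpp, coordinates))
}
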