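# Synthetic toy systems: a multi-helix "receptor" bundle with a binding
# cavity, a small rigid ring ligand with a polar N-S head, and a water
# droplet. Everything is generated in code, deterministically for a fixed
# seed, so the whole pipeline is testable without external structures.

#' Generate a toy helical-bundle receptor with a bound ligand
#'
#' Ideal vertical alpha-helices (rise 1.5 A, 100 deg per residue, C-alpha
#' radius 2.3 A), each residue carrying a C-alpha and a pseudo side-chain
#' bead CB placed 1.9 A radially outward from the bundle axis (so side
#' chains line the outer surface and the core stays open), packed around a
#' central axis closely enough that neighbouring helices form native
#' contacts. The ligand sits on the bundle
#' axis in the open binding pocket at the extracellular mouth: a
#' six-membered planar carbon ring with an N-S polar head (an N-H donor and
#' a thioamide-like acceptor) mimicking the ring + thiourea chemistry of the
#' bitter-taste agonists at toy scale. Its height is chosen as the lowest
#' position with at least 3.2 A clearance to the protein (outside the
#' steep part of the Lennard-Jones wall).
#'
#' @param n_helices number of helices (default 4)
#' @param residues_per_helix residues per helix (default 10)
#' @param cavity_radius controls the bundle aperture (helix axis circle
#'   radius = `cavity_radius + 0.2` A); smaller values close the mouth until
#'   the ligand no longer fits
#' @param ligand include the ligand (default TRUE)
#' @param seed reserved for randomised variants; the default geometry is
#'   deterministic
#' @return list with `topology` and `coordinates` (native structure)
#' @export
make_toy_bundle <- function(n_helices = 4L, residues_per_helix = 10L,
                            cavity_radius = 5.0, ligand = TRUE, seed = 1L) {
  stopifnot(n_helices >= 2, residues_per_helix >= 4, cavity_radius > 0)
  rise <- 1.5; twist <- 100 * pi / 180
  r_ca <- 2.3
  height <- rise * (residues_per_helix - 1)
  r_axis <- cavity_radius + 0.2

  atoms <- list(); xyz <- list(); bonds <- list()
  serial <- 0L; resid <- 0L; aidx <- 0L
  add_atom <- function(name, element, resname, chain, pos) {
    serial <<- serial + 1L; aidx <<- aidx + 1L
    atoms[[aidx]] <<- data.frame(serial = serial, name = name,
                                 element = element, resid = resid,
                                 resname = resname, chain = chain,
                                 stringsAsFactors = FALSE)
    xyz[[aidx]] <<- pos
    aidx
  }

  for (h in seq_len(n_helices)) {
    phi <- 2 * pi * (h - 1) / n_helices
    axis <- c(r_axis * cos(phi), r_axis * sin(phi))
    chain <- LETTERS[h]
    prev_ca <- NA_integer_
    for (i in seq_len(residues_per_helix)) {
      resid <- resid + 1L
      z <- rise * (i - 1)
      ang <- twist * (i - 1) + phi # per-helix phase offset
      ca_xy <- axis + r_ca * c(cos(ang), sin(ang))
      u <- ca_xy / sqrt(sum(ca_xy^2)) # radially outward from the bundle axis
      ca <- add_atom("CA", "C", "ALA", chain, c(ca_xy, z))
      cb <- add_atom("CB", "C", "ALA", chain, c(ca_xy + 1.9 * u, z))
      bonds[[length(bonds) + 1]] <- c(ca, cb)
      if (!is.na(prev_ca)) bonds[[length(bonds) + 1]] <- c(prev_ca, ca)
      prev_ca <- ca
    }
  }

  if (ligand) {
    # the aperture must be wide enough that the ligand can nest in the
    # mouth at all (its heavy atoms reach ~3.1 A from the axis)
    if (cavity_radius < 3.0) {
      stop("cavity too small for the ligand (aperture radius ", cavity_radius,
           " A); increase cavity_radius")
    }
    resid <- resid + 1L
    ring_r <- 1.39
    lig_idx <- integer(0)
    lig_pos <- list()
    for (k in 1:6) {
      a <- 2 * pi * (k - 1) / 6
      lig_pos[[k]] <- c(ring_r * cos(a), ring_r * sin(a), 0)
    }
    nn <- lig_pos[[1]] + c(1.35, 0, 0)                       # N on C1
    sv <- nn + 1.65 * c(cos(-pi / 3), sin(-pi / 3), 0)       # S off N
    hv <- nn + 1.01 * c(cos(pi / 3), sin(pi / 3), 0)         # H on N
    lig_pos[[7]] <- nn; lig_pos[[8]] <- sv; lig_pos[[9]] <- hv
    # centre the ligand heavy atoms on the bundle axis, then find the
    # lowest mouth position with >= 3.2 A clearance to the protein
    pm <- do.call(rbind, lig_pos)
    ctr <- colMeans(pm[1:8, ])
    pm <- sweep(pm, 2, ctr)
    prot_heavy <- do.call(rbind, xyz)
    zlig <- NA_real_
    for (dz in seq(0, 5, by = 0.25)) {
      trial <- pm + matrix(c(0, 0, height + 1.0 + dz), 9, 3, byrow = TRUE)
      d2 <- Inf
      for (k in 1:8) {
        d2 <- min(d2, min((prot_heavy[, 1] - trial[k, 1])^2 +
                            (prot_heavy[, 2] - trial[k, 2])^2 +
                            (prot_heavy[, 3] - trial[k, 3])^2))
      }
      if (sqrt(d2) >= 3.2) { zlig <- height + 1.0 + dz; break }
    }
    if (is.na(zlig)) {
      stop("cavity too small for the ligand; increase cavity_radius")
    }
    pm <- pm + matrix(c(0, 0, zlig), 9, 3, byrow = TRUE)
    names_l <- c(paste0("C", 1:6), "N1", "S1", "HN1")
    elem_l <- c(rep("C", 6), "N", "S", "H")
    for (k in 1:9) {
      lig_idx[k] <- add_atom(names_l[k], elem_l[k], "LIG", "L", pm[k, ])
    }
    ring_bonds <- cbind(lig_idx[1:6], lig_idx[c(2:6, 1)])
    extra <- rbind(c(lig_idx[1], lig_idx[7]), # C1-N
                   c(lig_idx[7], lig_idx[8]), # N-S
                   c(lig_idx[7], lig_idx[9])) # N-H
    for (r in seq_len(nrow(ring_bonds))) bonds[[length(bonds) + 1]] <- ring_bonds[r, ]
    for (r in seq_len(nrow(extra))) bonds[[length(bonds) + 1]] <- extra[r, ]
  }

  topology <- make_topology(do.call(rbind, atoms),
                            bonds = do.call(rbind, bonds))
  coords <- do.call(rbind, xyz)
  # helices must not clash with each other (heavy-atom minimum 1.5 A)
  ch <- topology$atoms$chain
  heavy_idx <- which(!topology$atoms$is_hydrogen)
  dmin_hel <- Inf
  for (i in heavy_idx) {
    for (j in heavy_idx) {
      if (j <= i || ch[i] == ch[j]) next
      dmin_hel <- min(dmin_hel, sqrt(sum((coords[i, ] - coords[j, ])^2)))
    }
  }
  if (is.finite(dmin_hel) && dmin_hel < 1.5) {
    stop("cavity too small: inter-helix steric clash (",
         round(dmin_hel, 2), " A); increase cavity_radius")
  }
  if (ligand) {
    # the cavity must accommodate the ligand
    lig_atoms <- topology$ligand
    prot <- setdiff(which(!topology$atoms$is_hydrogen), lig_atoms)
    ligh <- lig_atoms[!topology$atoms$is_hydrogen[lig_atoms]]
    dmin <- min_cross_distance(coords[ligh, , drop = FALSE],
                               coords[prot, , drop = FALSE])
    if (dmin < 1.5) {
      stop("cavity too small for the ligand (closest approach ",
           round(dmin, 2), " A); increase cavity_radius")
    }
  }
  list(topology = topology, coordinates = check_coords(topology, coords))
}

#' Add a droplet of rigid 3-site waters around a centre
#'
#' Waters are placed by rejection sampling inside the sphere, each oxygen at
#' least 2.4 A from every previously present heavy atom, with random rigid
#' orientations (SPC geometry). Deterministic for a fixed seed.
#'
#' @param topology an `mmcg_topology`
#' @param coordinates matching coordinates
#' @param n_waters number of waters to place
#' @param center droplet centre; default the ligand centroid (or the system
#'   centroid without a ligand)
#' @param radius droplet radius, Angstrom (default 15)
#' @param min_dist minimum O to heavy-atom distance, Angstrom
#' @param zmin optional floor: oxygens are only placed above this z (used
#'   to keep the droplet on the extracellular side of the lipid plane)
#' @param seed RNG seed
#' @param max_attempts rejection-sampling budget
#' @return list with augmented `topology` and `coordinates`
#' @export
solvate_droplet <- function(topology, coordinates, n_waters,
                            center = NULL, radius = 15.0, min_dist = 2.4,
                            zmin = NULL, seed = 1L, max_attempts = 1e5) {
  stopifnot(radius > 0, n_waters >= 0)
  coordinates <- check_coords(topology, coordinates)
  if (n_waters == 0) return(list(topology = topology, coordinates = coordinates))
  if (is.null(center)) {
    center <- if (length(topology$ligand) > 0) {
      colMeans(coordinates[topology$ligand, , drop = FALSE])
    } else {
      colMeans(coordinates)
    }
  }
  d_oh <- 1.0; half <- 109.47 * pi / 180 / 2

  heavy_xyz <- coordinates[!topology$atoms$is_hydrogen, , drop = FALSE]
  placed <- matrix(numeric(0), ncol = 3)
  o_pos <- matrix(NA_real_, n_waters, 3)
  # deterministic uniform stream from the engine RNG
  draw <- cpp_uniforms(as.numeric(seed), 1000, as.integer(max_attempts) * 3L)
  ptr <- 0L
  nxt <- function() { ptr <<- ptr + 1L; draw[ptr] }
  placed_n <- 0L
  attempts <- 0L
  while (placed_n < n_waters) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place ", n_waters, " waters in ", max_attempts,
           " attempts; try fewer waters or a larger droplet")
    }
    p <- center + (c(nxt(), nxt(), nxt()) * 2 - 1) * radius
    if (sum((p - center)^2) > radius^2) next
    if (!is.null(zmin) && p[3] < zmin) next
    all_heavy <- rbind(heavy_xyz, placed)
    d2 <- (all_heavy[, 1] - p[1])^2 + (all_heavy[, 2] - p[2])^2 +
      (all_heavy[, 3] - p[3])^2
    if (min(d2) < min_dist^2) next
    placed_n <- placed_n + 1L
    o_pos[placed_n, ] <- p
    placed <- rbind(placed, p)
  }

  # random rigid orientations from a second stream
  rot_draw <- cpp_uniforms(as.numeric(seed), 1001, n_waters * 2L)
  atoms <- list(); xyz <- list(); bonds <- list()
  serial0 <- max(topology$atoms$serial)
  resid0 <- max(topology$atoms$resid)
  n0 <- n_atoms(topology)
  for (w in seq_len(n_waters)) {
    theta <- acos(2 * rot_draw[2 * w - 1] - 1)
    phi <- 2 * pi * rot_draw[2 * w]
    u <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    # orthonormal partner for the H-H direction
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v <- ref - sum(ref * u) * u
    v <- v / sqrt(sum(v^2))
    o <- o_pos[w, ]
    h1 <- o + d_oh * (cos(half) * u + sin(half) * v)
    h2 <- o + d_oh * (cos(half) * u - sin(half) * v)
    rid <- resid0 + w
    base <- n0 + (w - 1) * 3
    atoms[[w]] <- data.frame(
      serial = serial0 + (w - 1) * 3 + 1:3,
      name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
      resid = rid, resname = "SOL", chain = "W", stringsAsFactors = FALSE)
    xyz[[w]] <- rbind(o, h1, h2)
    bonds[[w]] <- rbind(c(base + 1, base + 2), c(base + 1, base + 3))
  }
  new_atoms <- rbind(topology$atoms[, c("serial", "name", "element", "resid",
                                        "resname", "chain")],
                     do.call(rbind, atoms))
  new_bonds <- rbind(topology$bonds, do.call(rbind, bonds))
  new_topology <- make_topology(new_atoms, bonds = new_bonds)
  list(topology = new_topology,
       coordinates = check_coords(new_topology,
                                  rbind(coordinates, do.call(rbind, xyz))))
}

#' Complete toy receptor-ligand-water system
#'
#' Convenience wrapper: [make_toy_bundle()] followed by [solvate_droplet()],
#' with the cavity-lining residues (those with any heavy atom within
#' `cavity_shell` of the ligand) reported as the natural MM selection.
#'
#' @inheritParams make_toy_bundle
#' @inheritParams solvate_droplet
#' @param cavity_shell distance defining the cavity-lining (MM) residues, A
#' @return list with `topology`, `coordinates`, `mm_residues` and
#'   `wall_hints` (slab placement so the bundle is membrane-embedded with
#'   its mouth at the upper lipid-head plane and the droplet above it)
#' @export
make_toy_system <- function(n_helices = 4L, residues_per_helix = 10L,
                            cavity_radius = 5.0, n_waters = 60L,
                            droplet_radius = 15.0, cavity_shell = 6.0,
                            seed = 1L) {
  bundle <- make_toy_bundle(n_helices, residues_per_helix, cavity_radius,
                            ligand = TRUE, seed = seed)
  # the toy stands with its extracellular mouth at the upper lipid-head
  # plane: membrane slab below, droplet dome above
  height <- 1.5 * (residues_per_helix - 1)
  lipid_plane_z <- height + 1.0
  solv <- solvate_droplet(bundle$topology, bundle$coordinates,
                          n_waters = n_waters, radius = droplet_radius,
                          zmin = lipid_plane_z, seed = seed)
  topo <- solv$topology; coords <- solv$coordinates
  lig <- topo$ligand
  heavy <- !topo$atoms$is_hydrogen
  mm <- integer(0)
  for (r in protein_residues(topo)) {
    idx <- atoms_of_residue(topo, r)
    idx <- idx[heavy[idx]]
    d <- min_cross_distance(coords[idx, , drop = FALSE],
                            coords[lig[heavy[lig]], , drop = FALSE])
    if (d <= cavity_shell) mm <- c(mm, r)
  }
  if (length(mm) == 0) mm <- protein_residues(topo)[1]
  list(topology = topo, coordinates = coords, mm_residues = sort(mm),
       wall_hints = list(slab_center_z = lipid_plane_z - 31 / 2,
                         water_slab_wall = TRUE))
}

#' Reference trajectories with known ground truth
#'
#' Constructs analysis-layer test inputs directly (no dynamics): `static`
#' repeats the input frame; `two_pose_switch` holds the ligand in pose A for
#' a fraction of the frames and in a rigidly displaced pose B for the rest
#' (exactly two pose clusters with preset populations); `random_walk`
#' jitters the ligand around one pose with displacement vectors of norm at
#' most `3 * sigma` (guaranteeing a single cluster at a 1 A cutoff for small
#' sigma).
#'
#' @param topology an `mmcg_topology` with a ligand
#' @param coordinates base coordinates
#' @param model one of `"static"`, `"two_pose_switch"`, `"random_walk"`
#' @param n_frames number of frames
#' @param split fraction of frames in pose A (two_pose_switch)
#' @param displacement pose A to pose B shift, Angstrom (two_pose_switch)
#' @param sigma jitter scale, Angstrom (random_walk)
#' @param seed RNG seed
#' @return an `mmcg_trajectory`
#' @export
make_reference_trajectory <- function(topology, coordinates,
                                      model = c("static", "two_pose_switch",
                                                "random_walk"),
                                      n_frames = 100L, split = 0.7,
                                      displacement = 5.0, sigma = 0.1,
                                      seed = 1L) {
  model <- match.arg(model)
  coordinates <- check_coords(topology, coordinates)
  lig <- topology$ligand
  if (length(lig) == 0 && model != "static") {
    stop("reference trajectories need a ligand in the topology")
  }
  frames <- array(0, dim = c(n_atoms(topology), 3, n_frames))
  if (model == "static") {
    for (f in seq_len(n_frames)) frames[, , f] <- coordinates
  } else if (model == "two_pose_switch") {
    n_a <- round(split * n_frames)
    pose_b <- coordinates
    pose_b[lig, 1] <- pose_b[lig, 1] + displacement
    for (f in seq_len(n_frames)) {
      frames[, , f] <- if (f <= n_a) coordinates else pose_b
    }
  } else {
    g <- matrix(cpp_gaussians(as.numeric(seed), 2000, 3L * n_frames),
                ncol = 3, byrow = TRUE)
    for (f in seq_len(n_frames)) {
      shift <- g[f, ] * sigma
      nrm <- sqrt(sum(shift^2))
      if (nrm > 3 * sigma) shift <- shift * (3 * sigma / nrm)
      x <- coordinates
      x[lig, ] <- sweep(x[lig, , drop = FALSE], 2, -shift)
      frames[, , f] <- x
    }
  }
  structure(
    list(topology = topology, frames = frames,
         steps = seq_len(n_frames) - 1L, times = as.numeric(seq_len(n_frames) - 1),
         replica = rep(1L, n_frames), energy_log = NULL, final = NULL,
         params = NULL),
    class = "mmcg_trajectory"
  )
}
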