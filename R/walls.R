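#' Build the implicit-membrane wall system and water-droplet wall
#'
#' The membrane is replaced by half-harmonic confining walls built from the
#' initial structure: two planar walls at the lipid-head heights
#' (`slab_center_z +/- slab_thickness/2`, thickness ~31 A), hemispheric caps
#' over the extracellular and cytoplasmic ends, and a lateral "membrane
#' wall" that follows the initial protein surface (union of spheres of
#' radius `lateral_offset`, 2.0 A, around the initial membrane-zone C-alpha
#' positions). Water is confined by a spherical droplet wall (radius 15 A)
#' centred on the ligand centroid (recomputed every step) or on a fixed
#' point.
#'
#' Particle sets are fixed at build time: membrane-zone protein particles
#' (initial z inside the slab) feel the planar and lateral walls; protein
#' particles initially beyond a planar wall feel the corresponding cap; the
#' droplet wall acts on water oxygens only (hydrogens follow through the
#' rigid-water constraints).
#'
#' @param topology the (simulation) `mmcg_topology`
#' @param coordinates initial coordinates, `n x 3`, Angstrom
#' @param slab_thickness implicit membrane thickness, Angstrom
#' @param slab_center_z slab centre; default the mean protein z
#' @param lateral_offset lateral wall distance from the initial C-alpha
#'   positions, Angstrom
#' @param droplet_radius water droplet radius, Angstrom
#' @param droplet_mode `"ligand_centroid"` (moving centre) or `"fixed"`
#' @param droplet_center fixed droplet centre (used when mode is `"fixed"`;
#'   defaults to the ligand centroid, or the protein centroid without ligand)
#' @param k_wall,k_drop wall stiffnesses, kJ/mol/A^2
#' @param water_slab_wall keep water oxygens above the upper lipid-head
#'   plane (`zhi`), the plane's role in the implicit-membrane model; enable
#'   for droplets on the extracellular side
#' @param cap_margin margin added to the 95th-percentile cap radius, Angstrom
#' @return an `mmcg_walls` object; if the protein principal axis is more
#'   than 30 degrees from z a warning is issued and the aligned coordinates
#'   are stored in `attr(walls, "coordinates")`
#' @export
build_walls <- function(topology, coordinates,
                        slab_thickness = 31.0, slab_center_z = NULL,
                        lateral_offset = 2.0,
                        droplet_radius = 15.0,
                        droplet_mode = c("ligand_centroid", "fixed"),
                        droplet_center = NULL,
                        k_wall = 250, k_drop = 250, cap_margin = 5.0,
                        water_slab_wall = FALSE) {
  coordinates <- check_coords(topology, coordinates)
  droplet_mode <- match.arg(droplet_mode)
  stopifnot(slab_thickness > 0, lateral_offset >= 0, droplet_radius > 0)

  prot_res <- protein_residues(topology)
  prot_atoms <- which(topology$atoms$resid %in% prot_res)
  if (length(prot_atoms) == 0) stop("no protein atoms to build walls around")

  realigned <- FALSE
  ca <- calpha_indices(topology, residues = prot_res)
  axis <- if (length(ca) >= 3) bundle_axis(topology, coordinates, ca) else c(0, 0, 1)
  tilt <- acos(min(1, abs(axis[3]))) * 180 / pi
  if (tilt > 30) {
    warning(sprintf(
      "protein principal axis is %.0f deg from z; auto-aligning to the membrane normal",
      tilt))
    R <- rotation_onto_z(axis)
    ctr <- colMeans(coordinates[prot_atoms, , drop = FALSE])
    coordinates <- sweep(coordinates, 2, ctr) %*% t(R)
    coordinates <- sweep(coordinates, 2, ctr, `+`)
    realigned <- TRUE
  }

  if (is.null(slab_center_z)) {
    slab_center_z <- mean(coordinates[prot_atoms, 3])
  }
  zlo <- slab_center_z - slab_thickness / 2
  zhi <- slab_center_z + slab_thickness / 2

  z <- coordinates[, 3]
  in_slab <- prot_atoms[z[prot_atoms] >= zlo & z[prot_atoms] <= zhi]
  above <- prot_atoms[z[prot_atoms] > zhi]
  below <- prot_atoms[z[prot_atoms] < zlo]

  cap_geometry <- function(idx) {
    if (length(idx) == 0) {
      return(list(center = c(0, 0, 0), radius = 0, idx = integer(0)))
    }
    ctr <- colMeans(coordinates[idx, , drop = FALSE])
    d <- sqrt(rowSums(sweep(coordinates[idx, , drop = FALSE], 2, ctr)^2))
    list(center = ctr, radius = unname(stats::quantile(d, 0.95)) + cap_margin,
         idx = idx)
  }
  cap1 <- cap_geometry(above) # extracellular
  cap2 <- cap_geometry(below) # cytoplasmic

  ca_mem <- ca[z[ca] >= zlo & z[ca] <= zhi]
  anchors <- coordinates[ca_mem, , drop = FALSE]

  water_o <- topology$water[toupper(topology$atoms$element[topology$water]) == "O"]
  if (droplet_mode == "ligand_centroid" && length(topology$ligand) == 0) {
    droplet_mode <- "fixed"
  }
  if (is.null(droplet_center)) {
    droplet_center <- if (length(topology$ligand) > 0) {
      colMeans(coordinates[topology$ligand, , drop = FALSE])
    } else {
      colMeans(coordinates[prot_atoms, , drop = FALSE])
    }
  }

  walls <- structure(
    list(
      slab_center_z = slab_center_z, slab_thickness = slab_thickness,
      zlo = zlo, zhi = zhi, k_wall = k_wall, k_drop = k_drop,
      cap1 = cap1, cap2 = cap2,
      anchors = anchors, lateral_offset = lateral_offset,
      lateral_idx = in_slab,
      droplet = list(mode = droplet_mode, center = as.numeric(droplet_center),
                     radius = droplet_radius, water_o = water_o,
                     ligand = topology$ligand),
      water_slab_wall = isTRUE(water_slab_wall)
    ),
    class = "mmcg_walls"
  )
  if (realigned) attr(walls, "coordinates") <- coordinates
  walls
}

# membrane normal estimate: mean of the per-chain C-alpha end-to-end
# directions (sign-aligned); falls back to the first principal axis for a
# single short chain
bundle_axis <- function(topology, coordinates, ca) {
  chains <- unique(topology$atoms$chain[ca])
  dirs <- list()
  for (ch in chains) {
    idx <- ca[topology$atoms$chain[ca] == ch]
    if (length(idx) < 2) next
    v <- coordinates[idx[length(idx)], ] - coordinates[idx[1], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) next
    v <- v / nv
    if (length(dirs) > 0 && sum(v * dirs[[1]]) < 0) v <- -v
    dirs[[length(dirs) + 1]] <- v
  }
  if (length(dirs) == 0) {
    pts <- coordinates[ca, , drop = FALSE]
    return(prcomp(pts, center = TRUE)$rotation[, 1])
  }
  axis <- Reduce(`+`, dirs) / length(dirs)
  axis / sqrt(sum(axis^2))
}

rotation_onto_z <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  if (a[3] < 0) a <- -a
  z <- c(0, 0, 1)
  v <- c(a[2] * z[3] - a[3] * z[2], a[3] * z[1] - a[1] * z[3],
         a[1] * z[2] - a[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * z)
  if (s < 1e-12) return(diag(3))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

#' @export
print.mmcg_walls <- function(x, ...) {
  cat("mmcg implicit-membrane walls:\n")
  cat(sprintf("  slab: z in [%.1f, %.1f] A (thickness %.1f), k = %.0f kJ/mol/A^2\n",
              x$zlo, x$zhi, x$slab_thickness, x$k_wall))
  cat(sprintf("  caps: %d / %d particles, radii %.1f / %.1f A\n",
              length(x$cap1$idx), length(x$cap2$idx), x$cap1$radius, x$cap2$radius))
  cat(sprintf("  lateral wall: %d anchors, offset %.1f A, %d particles\n",
              nrow(x$anchors), x$lateral_offset, length(x$lateral_idx)))
  cat(sprintf("  droplet: mode %s, radius %.1f A, %d water oxygens\n",
              x$droplet$mode, x$droplet$radius, length(x$droplet$water_o)))
  invisible(x)
}

walls_cpp <- function(walls, enabled = TRUE) {
  if (is.null(walls) || !enabled) return(list(enabled = FALSE))
  list(
    enabled = TRUE,
    k_wall = walls$k_wall, k_drop = walls$k_drop,
    zlo = walls$zlo, zhi = walls$zhi,
    slab_idx = as.integer(walls$lateral_idx),
    cap1_center = as.numeric(walls$cap1$center), cap1_radius = walls$cap1$radius,
    cap1_idx = as.integer(walls$cap1$idx),
    cap2_center = as.numeric(walls$cap2$center), cap2_radius = walls$cap2$radius,
    cap2_idx = as.integer(walls$cap2$idx),
    anchors = if (nrow(walls$anchors) > 0) walls$anchors else
      matrix(numeric(0), ncol = 3),
    lat_offset = walls$lateral_offset,
    lat_idx = as.integer(walls$lateral_idx),
    drop_mode = if (walls$droplet$mode == "ligand_centroid") 1L else 0L,
    drop_center = walls$droplet$center,
    drop_radius = walls$droplet$radius,
    drop_idx = as.integer(walls$droplet$water_o),
    lig_idx = as.integer(walls$droplet$ligand),
    water_plane = isTRUE(walls$water_slab_wall),
    water_zmin = walls$zhi
  )
}

#' Wall energy and forces
#'
#' Half-harmonic penalty `k/2 d^2` for penetration depth `d` beyond each
#' wall surface; zero inside the allowed region, with forces pointing back
#' inside. With a moving (ligand-centroid) droplet centre, the reaction
#' force on the ligand atoms is included so the forces remain the exact
#' negative gradient of the energy.
#'
#' @param walls an `mmcg_walls` object
#' @param topology the matching `mmcg_topology`
#' @param coordinates `n x 3` matrix, Angstrom
#' @return an `mmcg_energy_report` (only the `wall` term is nonzero)
#' @export
wall_energy_forces <- function(walls, topology, coordinates) {
  coordinates <- check_coords(topology, coordinates)
  sys <- cpp_sys_skeleton(n_atoms(topology), topology$atoms$mass)
  sys$walls <- walls_cpp(walls)
  energy_report(cpp_energy_forces(sys, coordinates))
}

#' Per-frame wall penetration report
#'
#' Quality control for the confinement model: for every frame and every
#' wall, the maximum penetration depth and the offending particle.
#'
#' @param trajectory an `mmcg_trajectory`
#' @param walls an `mmcg_walls` object
#' @return tibble with columns `frame`, `wall`, `max_penetration` (A),
#'   `particle` (atom index, NA when nothing penetrates)
#' @export
containment_report <- function(trajectory, walls) {
  nf <- n_frames(trajectory)
  if (nf == 0) stop("trajectory is empty")
  out <- vector("list", nf)
  for (fr in seq_len(nf)) {
    x <- get_frame(trajectory, fr)
    pen <- list(
      slab_upper = wall_penetration_z(x, walls$lateral_idx, walls$zhi, upper = TRUE),
      slab_lower = wall_penetration_z(x, walls$lateral_idx, walls$zlo, upper = FALSE),
      cap_extracellular = wall_penetration_sphere(x, walls$cap1$idx,
                                                  walls$cap1$center, walls$cap1$radius),
      cap_cytoplasmic = wall_penetration_sphere(x, walls$cap2$idx,
                                                walls$cap2$center, walls$cap2$radius),
      lateral = wall_penetration_lateral(x, walls$lateral_idx, walls$anchors,
                                         walls$lateral_offset),
      droplet = wall_penetration_droplet(x, walls),
      water_plane = if (isTRUE(walls$water_slab_wall)) {
        wall_penetration_z(x, walls$droplet$water_o, walls$zhi, upper = FALSE)
      } else {
        list(depth = 0, particle = NA_integer_)
      }
    )
    out[[fr]] <- tibble::tibble(
      frame = fr,
      wall = names(pen),
      max_penetration = unname(vapply(pen, function(p) p$depth, numeric(1))),
      particle = unname(vapply(pen, function(p) as.integer(p$particle),
                               integer(1)))
    )
  }
  do.call(rbind, out)
}

wall_penetration_z <- function(x, idx, zwall, upper) {
  if (length(idx) == 0) return(list(depth = 0, particle = NA_integer_))
  d <- if (upper) x[idx, 3] - zwall else zwall - x[idx, 3]
  w <- which.max(d)
  if (d[w] <= 0) list(depth = 0, particle = NA_integer_)
  else list(depth = d[w], particle = idx[w])
}

wall_penetration_sphere <- function(x, idx, center, radius) {
  if (length(idx) == 0) return(list(depth = 0, particle = NA_integer_))
  d <- sqrt(rowSums(sweep(x[idx, , drop = FALSE], 2, center)^2)) - radius
  w <- which.max(d)
  if (d[w] <= 0) list(depth = 0, particle = NA_integer_)
  else list(depth = d[w], particle = idx[w])
}

wall_penetration_lateral <- function(x, idx, anchors, offset, beta = 10) {
  if (length(idx) == 0 || nrow(anchors) == 0) {
    return(list(depth = 0, particle = NA_integer_))
  }
  depth <- -Inf; particle <- NA_integer_
  for (p in idx) {
    d <- sqrt((anchors[, 1] - x[p, 1])^2 + (anchors[, 2] - x[p, 2])^2 +
                (anchors[, 3] - x[p, 3])^2)
    dmin <- min(d)
    dsoft <- dmin - log(sum(exp(-beta * (d - dmin)))) / beta
    pen <- dsoft - offset
    if (pen > depth) { depth <- pen; particle <- p }
  }
  if (depth <= 0) list(depth = 0, particle = NA_integer_)
  else list(depth = depth, particle = particle)
}

wall_penetration_droplet <- function(x, walls) {
  idx <- walls$droplet$water_o
  if (length(idx) == 0) return(list(depth = 0, particle = NA_integer_))
  center <- if (walls$droplet$mode == "ligand_centroid" &&
                length(walls$droplet$ligand) > 0) {
    colMeans(x[walls$droplet$ligand, , drop = FALSE])
  } else {
    walls$droplet$center
  }
  wall_penetration_sphere(x, idx, center, walls$droplet$radius)
}
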