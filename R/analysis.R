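#' Kabsch least-squares superposition
#'
#' Optimal rigid superposition (proper rotation, det = +1) of the selected
#' atoms of `mobile` onto `reference`, via the SVD of the covariance matrix.
#'
#' @param mobile,reference coordinate matrices (`n x 3`)
#' @param selection optional atom indices used for the fit (defaults to all;
#'   both structures use the same selection)
#' @return list with `rotation` (3x3), `translation` (length 3; the fitted
#'   transform is `x %*% t(R) + t`), and `rmsd` (A) over the selection
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3) stop("selection must contain at least 3 atoms")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selections differ in length")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity guard: rank of the centred cloud
  if (qr(A0)$rank < 2 || qr(B0)$rank < 2) {
    stop("degenerate (collinear) selection: superposition undefined")
  }
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cb - as.numeric(R %*% ca)
  fitted <- A %*% t(R) + matrix(t_vec, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

apply_transform <- function(coords, transform) {
  coords %*% t(transform$rotation) +
    matrix(transform$translation, nrow(coords), 3, byrow = TRUE)
}

#' C-alpha RMSD time series
#'
#' Per-frame RMSD after least-squares superposition on the selection.
#' An optional residue exclusion (e.g. a mobile loop) is applied to both
#' the fit and the measurement.
#'
#' @param trajectory an `mmcg_trajectory`
#' @param reference reference coordinates (defaults to frame 1)
#' @param selection atom indices; default the protein C-alphas
#' @param exclude_residues residue indices removed from the selection
#' @return tibble with `frame`, `time`, `replica`, `rmsd`
#' @export
rmsd_timeseries <- function(trajectory, reference = NULL, selection = NULL,
                            exclude_residues = NULL) {
  topo <- trajectory$topology
  if (is.null(selection)) {
    selection <- calpha_indices(topo, residues = protein_residues(topo))
  }
  if (!is.null(exclude_residues)) {
    selection <- selection[!topo$atoms$resid[selection] %in% exclude_residues]
  }
  if (length(selection) == 0) stop("empty selection after residue exclusion")
  if (is.null(reference)) reference <- get_frame(trajectory, 1)
  nf <- n_frames(trajectory)
  rmsd <- vapply(seq_len(nf), function(i) {
    kabsch_superpose(get_frame(trajectory, i), reference, selection)$rmsd
  }, numeric(1))
  tibble::tibble(frame = seq_len(nf), time = trajectory$times,
                 replica = trajectory$replica, rmsd = rmsd)
}

#' Superpose every frame on a common reference
#'
#' Backbone pre-alignment used before ligand-pose analysis: each frame is
#' rigidly transformed so its selection (default: protein C-alphas) best
#' fits the reference frame.
#'
#' @inheritParams rmsd_timeseries
#' @param reference_frame frame index used as the reference (default 1)
#' @return the aligned `mmcg_trajectory`
#' @export
prealign_trajectory <- function(trajectory, reference_frame = 1L,
                                selection = NULL) {
  topo <- trajectory$topology
  if (is.null(selection)) {
    selection <- calpha_indices(topo, residues = protein_residues(topo))
  }
  ref <- get_frame(trajectory, reference_frame)
  out <- trajectory
  for (i in seq_len(n_frames(trajectory))) {
    tr <- kabsch_superpose(get_frame(trajectory, i), ref, selection)
    out$frames[, , i] <- apply_transform(get_frame(trajectory, i), tr)
  }
  attr(out, "prealigned") <- TRUE
  out
}

#' Ligand-pose distance between two frames
#'
#' RMSD over the ligand atoms with no further fitting; on frames pre-aligned
#' on the protein backbone this measures the ligand's pose (position and
#' orientation in the binding site), not just its conformation.
#'
#' @param frame_a,frame_b coordinate matrices
#' @param topology the matching `mmcg_topology` (provides the ligand atoms)
#' @return distance, Angstrom
#' @export
ligand_pose_distance <- function(frame_a, frame_b, topology) {
  lig <- topology$ligand
  if (length(lig) == 0) stop("topology has no ligand atoms")
  sqrt(mean(rowSums((frame_a[lig, , drop = FALSE] -
                       frame_b[lig, , drop = FALSE])^2)))
}

#' Greedy largest-neighborhood (Daura) clustering of ligand poses
#'
#' Frames are pre-aligned on the protein backbone, pairwise ligand-pose
#' distances are computed, and clusters are extracted greedily: the frame
#' with the most neighbors within the cutoff becomes a cluster centre, the
#' cluster is removed, and the procedure repeats. Ties are broken by the
#' lowest frame index. The production analysis uses a 1 A cutoff.
#'
#' @param trajectory an `mmcg_trajectory`, or a precomputed symmetric
#'   distance matrix
#' @param cutoff neighbor cutoff, Angstrom (default 1.0)
#' @param metric `"ligand_pose"` (pre-align then ligand RMSD) or `"calpha"`
#'   (C-alpha RMSD after superposition)
#' @param prealign pre-align frames before measuring (default TRUE;
#'   ignored for a distance-matrix input)
#' @return an `mmcg_clusters` object: tibble of clusters (centre frame,
#'   size, population) plus per-cluster member lists
#' @export
daura_cluster <- function(trajectory, cutoff = 1.0,
                          metric = c("ligand_pose", "calpha"),
                          prealign = TRUE) {
  metric <- match.arg(metric)
  if (is.matrix(trajectory)) {
    D <- trajectory
    metric <- "precomputed"
  } else {
    D <- pose_distance_matrix(trajectory, metric = metric, prealign = prealign)
  }
  nf <- nrow(D)
  if (nf < 1) stop("need at least one frame")

  remaining <- rep(TRUE, nf)
  members <- list()
  centers <- integer(0)
  while (any(remaining)) {
    idx <- which(remaining)
    # neighbor counts within the cutoff (self included)
    counts <- vapply(idx, function(i) sum(D[i, idx] <= cutoff), integer(1))
    center <- idx[which.max(counts)] # which.max takes the first = lowest index
    mem <- idx[D[center, idx] <= cutoff]
    members[[length(members) + 1]] <- mem
    centers <- c(centers, center)
    remaining[mem] <- FALSE
  }
  ord <- order(-vapply(members, length, integer(1)),
               vapply(members, min, integer(1)))
  members <- members[ord]
  centers <- centers[ord]
  sizes <- vapply(members, length, integer(1))
  structure(
    list(clusters = tibble::tibble(
      cluster = seq_along(centers),
      center_frame = centers,
      size = sizes,
      population = sizes / nf
    ),
    members = members, metric = metric, cutoff = cutoff, n_frames = nf),
    class = "mmcg_clusters"
  )
}

pose_distance_matrix <- function(trajectory, metric = "ligand_pose",
                                 prealign = TRUE) {
  nf <- n_frames(trajectory)
  if (metric == "ligand_pose" && prealign &&
      !isTRUE(attr(trajectory, "prealigned"))) {
    trajectory <- prealign_trajectory(trajectory)
  }
  D <- matrix(0, nf, nf)
  if (metric == "ligand_pose") {
    lig <- trajectory$topology$ligand
    if (length(lig) == 0) stop("topology has no ligand atoms")
    coords <- lapply(seq_len(nf), function(i) get_frame(trajectory, i)[lig, , drop = FALSE])
    for (i in seq_len(nf - 1)) {
      for (j in seq.int(i + 1, nf)) {
        d <- sqrt(mean(rowSums((coords[[i]] - coords[[j]])^2)))
        D[i, j] <- d; D[j, i] <- d
      }
    }
  } else {
    sel <- calpha_indices(trajectory$topology,
                          residues = protein_residues(trajectory$topology))
    for (i in seq_len(nf - 1)) {
      for (j in seq.int(i + 1, nf)) {
        d <- kabsch_superpose(get_frame(trajectory, i),
                              get_frame(trajectory, j), sel)$rmsd
        D[i, j] <- d; D[j, i] <- d
      }
    }
  }
  D
}

#' @export
print.mmcg_clusters <- function(x, ...) {
  cat("mmcg pose clustering (", x$metric, ", cutoff ", x$cutoff, " A): ",
      nrow(x$clusters), " cluster(s) over ", x$n_frames, " frames\n", sep = "")
  print(utils::head(x$clusters, 10))
  invisible(x)
}

#' @rdname daura_cluster
#' @param x an `mmcg_clusters` object
#' @param ... unused
#' @export
tidy.mmcg_clusters <- function(x, ...) x$clusters

#' @rdname daura_cluster
#' @export
glance.mmcg_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters), n_frames = x$n_frames,
                 cutoff = x$cutoff,
                 top2_coverage = sum(utils::head(x$clusters$population, 2)))
}

#' Central structure of a cluster
#'
#' The cluster-centre frame: the member that had the most within-cutoff
#' neighbors when the cluster was extracted.
#'
#' @param clusters an `mmcg_clusters` object
#' @param trajectory the clustered `mmcg_trajectory`
#' @param cluster cluster index (1 = most populated)
#' @return coordinate matrix of the central frame, with attributes `frame`
#' @export
central_structure <- function(clusters, trajectory, cluster = 1L) {
  if (cluster < 1 || cluster > nrow(clusters$clusters)) {
    stop("cluster index ", cluster, " out of range")
  }
  fr <- clusters$clusters$center_frame[cluster]
  structure(get_frame(trajectory, fr), frame = fr)
}

#' Hydrogen-bond geometry series
#'
#' For each frame and each donor-hydrogen-acceptor triple: the
#' donor-acceptor distance, the D-H...A angle, and whether the geometric
#' criteria are met (defaults: D-A <= 3.5 A and angle >= 130 deg; the
#' distances are reported regardless of the angle, so distance
#' distributions do not depend on the angle choice).
#'
#' @param trajectory an `mmcg_trajectory`
#' @param triples data frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom indices) and optionally `label`
#' @param max_distance donor-acceptor distance criterion, Angstrom
#' @param min_angle D-H...A angle criterion, degrees
#' @return tibble with `frame`, `time`, `label`, `distance`, `angle`,
#'   `hbond`
#' @export
hbond_series <- function(trajectory, triples, max_distance = 3.5,
                         min_angle = 130) {
  stopifnot(is.data.frame(triples),
            all(c("donor", "hydrogen", "acceptor") %in% names(triples)))
  if (max_distance < 0) stop("max_distance must be nonnegative")
  if (min_angle <= 0 || min_angle > 180) stop("min_angle must be in (0, 180]")
  n <- n_atoms(trajectory$topology)
  idx <- c(triples$donor, triples$hydrogen, triples$acceptor)
  if (any(idx < 1 | idx > n)) stop("atom index out of range in triples")
  if (is.null(triples$label)) {
    a <- trajectory$topology$atoms
    triples$label <- paste0(a$resname[triples$donor], a$resid[triples$donor],
                            "-", a$name[triples$donor], " ... ",
                            a$resname[triples$acceptor], a$resid[triples$acceptor],
                            "-", a$name[triples$acceptor])
  }
  out <- vector("list", n_frames(trajectory))
  for (f in seq_len(n_frames(trajectory))) {
    x <- get_frame(trajectory, f)
    d <- sqrt(rowSums((x[triples$donor, , drop = FALSE] -
                         x[triples$acceptor, , drop = FALSE])^2))
    hv <- x[triples$donor, , drop = FALSE] - x[triples$hydrogen, , drop = FALSE]
    av <- x[triples$acceptor, , drop = FALSE] - x[triples$hydrogen, , drop = FALSE]
    cosang <- rowSums(hv * av) /
      (sqrt(rowSums(hv^2)) * sqrt(rowSums(av^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    out[[f]] <- tibble::tibble(
      frame = f, time = trajectory$times[f], label = triples$label,
      distance = d, angle = ang,
      hbond = d <= max_distance & ang >= min_angle
    )
  }
  do.call(rbind, out)
}

#' Histogram of donor-acceptor distances
#'
#' Distance-distribution summary of an [hbond_series()] result (the form the
#' production analysis plots per H-bond pair).
#'
#' @param series tibble from [hbond_series()]
#' @param breaks histogram bin edges, Angstrom
#' @return tibble with `label`, `bin_mid`, `count`
#' @export
hbond_histogram <- function(series, breaks = seq(0, 10, by = 0.1)) {
  out <- list()
  for (lb in unique(series$label)) {
    d <- series$distance[series$label == lb]
    d <- d[d >= min(breaks) & d <= max(breaks)]
    h <- hist(d, breaks = breaks, plot = FALSE)
    out[[lb]] <- tibble::tibble(label = lb, bin_mid = h$mids, count = h$counts)
  }
  do.call(rbind, out)
}

#' Labeled distance table for a structure
#'
#' Computes labeled distances in one frame: atom-atom distances, distances
#' between centroids of named rings, or side-chain-centroid to ring-centroid
#' distances (ring/side-chain selections are centroids of their heavy
#' atoms; the centroid convention is recorded in the output).
#'
#' @param frame coordinate matrix
#' @param topology the matching `mmcg_topology`
#' @param spec list of entries, each a list with `label`, `a`, `b`; `a`/`b`
#'   are either a single atom index, a vector of indices (centroid taken),
#'   or a named list of [select_atoms()] arguments
#' @return tibble with `label`, `distance` (A); attribute
#'   `convention = "centroid"`
#' @export
distance_table <- function(frame, topology, spec) {
  resolve <- function(sel) {
    if (is.numeric(sel)) {
      idx <- as.integer(sel)
    } else if (is.list(sel)) {
      idx <- do.call(select_atoms, c(list(topology = topology), sel))
    } else {
      stop("unknown selection type in distance spec")
    }
    if (length(idx) == 0) stop("selection matched no atoms")
    if (any(idx < 1 | idx > n_atoms(topology))) stop("selection index out of range")
    colMeans(frame[idx, , drop = FALSE])
  }
  rows <- lapply(spec, function(entry) {
    if (is.null(entry$label)) stop("distance spec entry without a label")
    pa <- resolve(entry$a)
    pb <- resolve(entry$b)
    tibble::tibble(label = entry$label,
                   distance = sqrt(sum((pa - pb)^2)))
  })
  out <- do.call(rbind, rows)
  attr(out, "convention") <- "centroid"
  out
}
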