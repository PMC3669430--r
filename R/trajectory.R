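# Trajectory container and its file formats.

new_trajectory <- function(topology, res, params, replica) {
  nf <- length(res$frame_steps)
  log <- tibble::as_tibble(as.data.frame(res$log))
  structure(
    list(topology = topology,
         frames = res$frames,
         velocity_frames = res$vel_frames,
         steps = res$frame_steps,
         times = res$frame_steps * params$timestep,
         replica = rep(as.integer(replica), nf),
         energy_log = log,
         final = list(coordinates = res$coords, velocities = res$velocities),
         params = params),
    class = "mmcg_trajectory"
  )
}

#' Number of frames in a trajectory
#' @param trajectory an `mmcg_trajectory`
#' @export
n_frames <- function(trajectory) {
  if (is.null(trajectory$frames)) 0L else dim(trajectory$frames)[3]
}

#' Extract one frame as a coordinate matrix
#' @param trajectory an `mmcg_trajectory`
#' @param i frame index (1-based)
#' @export
get_frame <- function(trajectory, i) {
  nf <- n_frames(trajectory)
  if (i < 1 || i > nf) stop("frame index ", i, " out of range (1..", nf, ")")
  trajectory$frames[, , i]
}

#' @export
print.mmcg_trajectory <- function(x, ...) {
  cat("mmcg trajectory:", n_frames(x), "frames,",
      n_atoms(x$topology), "particles, replica(s)",
      paste(unique(x$replica), collapse = ","), "\n")
  if (n_frames(x) > 0) {
    cat(sprintf("  time %.3f .. %.3f ps\n", x$times[1], x$times[n_frames(x)]))
  }
  invisible(x)
}

#' Concatenate replica trajectories
#'
#' Frames are concatenated in replica order (the analysis protocol joins
#' the replicas of a complex before clustering); replica ids are preserved
#' per frame and topologies must be congruent.
#'
#' @param trajectories list of `mmcg_trajectory` objects
#' @return a joined `mmcg_trajectory`
#' @export
join_replicas <- function(trajectories) {
  trajectories <- Filter(function(t) n_frames(t) > 0, trajectories)
  if (length(trajectories) == 0) stop("no non-empty trajectories to join")
  ref <- trajectories[[1]]
  for (t in trajectories[-1]) {
    if (n_atoms(t$topology) != n_atoms(ref$topology) ||
        !identical(t$topology$atoms$name, ref$topology$atoms$name)) {
      stop("topology mismatch between replicas")
    }
  }
  if (length(trajectories) == 1) return(ref)
  frames <- array(
    unlist(lapply(trajectories, function(t) t$frames), use.names = FALSE),
    dim = c(dim(ref$frames)[1], 3, sum(vapply(trajectories, n_frames, integer(1))))
  )
  structure(
    list(topology = ref$topology,
         frames = frames,
         steps = unlist(lapply(trajectories, function(t) t$steps)),
         times = unlist(lapply(trajectories, function(t) t$times)),
         replica = unlist(lapply(trajectories, function(t) t$replica)),
         energy_log = do.call(rbind, lapply(trajectories, function(t) t$energy_log)),
         final = trajectories[[length(trajectories)]]$final,
         params = ref$params),
    class = "mmcg_trajectory"
  )
}

#' Write a trajectory as a multi-model PDB file
#' @param trajectory an `mmcg_trajectory`
#' @param path output file
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  lines <- character(0)
  for (i in seq_len(n_frames(trajectory))) {
    lines <- c(lines, format_pdb_records(trajectory$topology,
                                         get_frame(trajectory, i), model = i))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a multi-model PDB file into a trajectory
#' @param path multi-model PDB written by [write_trajectory_pdb()]
#' @param timestep time per frame used to reconstruct times (ps)
#' @inheritParams make_topology
#' @export
read_trajectory_pdb <- function(path, timestep = 1,
                                water_resnames = c("HOH", "SOL", "WAT"),
                                ligand_resnames = c("LIG", "UNL", "UNK")) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  first <- read_pdb_first_model(path, water_resnames, ligand_resnames)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  n <- ncol(xyz) / 3
  frames <- array(0, dim = c(n, 3, nf))
  for (f in seq_len(nf)) {
    frames[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  structure(
    list(topology = first$topology, frames = frames,
         steps = seq_len(nf) - 1L, times = (seq_len(nf) - 1) * timestep,
         replica = rep(1L, nf), energy_log = NULL, final = NULL,
         params = NULL),
    class = "mmcg_trajectory"
  )
}

read_pdb_first_model <- function(path, water_resnames, ligand_resnames) {
  lines <- readLines(path, warn = FALSE)
  endm <- grep("^ENDMDL", lines)
  if (length(endm) > 0) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    writeLines(c(lines[seq_len(endm[1] - 1)],
                 lines[grep("^CONECT", lines)], "END"), tmp)
    read_pdb(tmp, water_resnames, ligand_resnames)
  } else {
    read_pdb(path, water_resnames, ligand_resnames)
  }
}

#' Write a trajectory in a simple XYZ-style frame format
#'
#' Plain-text format: per frame an atom-count line, a header line
#' `step=<n> time=<ps>`, then `name x y z` rows. Readable with
#' [read_trajectory_xyz()].
#'
#' @param trajectory an `mmcg_trajectory`
#' @param path output file
#' @export
write_trajectory_xyz <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  names <- trajectory$topology$atoms$name
  for (i in seq_len(n_frames(trajectory))) {
    x <- get_frame(trajectory, i)
    writeLines(c(sprintf("%d", nrow(x)),
                 sprintf("step=%d time=%.6f", trajectory$steps[i],
                         trajectory$times[i]),
                 sprintf("%-4s %12.6f %12.6f %12.6f",
                         names, x[, 1], x[, 2], x[, 3])), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @param topology the matching `mmcg_topology`
#' @export
read_trajectory_xyz <- function(path, topology) {
  lines <- readLines(path, warn = FALSE)
  n <- n_atoms(topology)
  block <- n + 2
  nf <- length(lines) %/% block
  frames <- array(0, dim = c(n, 3, nf))
  steps <- integer(nf)
  times <- numeric(nf)
  for (f in seq_len(nf)) {
    off <- (f - 1) * block
    hdr <- lines[off + 2]
    steps[f] <- as.integer(sub("^step=(\\d+).*$", "\\1", hdr))
    times[f] <- as.numeric(sub("^.*time=([0-9.eE+-]+).*$", "\\1", hdr))
    rows <- lines[(off + 3):(off + 2 + n)]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    frames[, , f] <- m
  }
  structure(
    list(topology = topology, frames = frames, steps = steps, times = times,
         replica = rep(1L, nf), energy_log = NULL, final = NULL, params = NULL),
    class = "mmcg_trajectory"
  )
}

#' Write the energy log as delimited text
#' @param trajectory an `mmcg_trajectory`
#' @param path output file (tab-separated, named columns)
#' @export
write_energy_log <- function(trajectory, path) {
  if (is.null(trajectory$energy_log)) stop("trajectory has no energy log")
  write.table(trajectory$energy_log, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' One-line summary of a trajectory
#' @param x an `mmcg_trajectory`
#' @param ... unused
#' @export
glance.mmcg_trajectory <- function(x, ...) {
  tibble::tibble(
    n_frames = n_frames(x),
    n_particles = n_atoms(x$topology),
    time_span = if (n_frames(x) > 0) x$times[n_frames(x)] - x$times[1] else 0,
    n_replicas = length(unique(x$replica)),
    mean_total_energy = if (!is.null(x$energy_log)) mean(x$energy_log$total)
    else NA_real_
  )
}
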