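#' Integrator parameters for stochastic (Langevin) dynamics
#'
#' The integrator is a symmetric BAOAB splitting: deterministic half kicks
#' and half drifts around an exact Ornstein-Uhlenbeck velocity update with
#' friction `gamma = 1/tau_friction` and noise amplitude
#' `sqrt(1 - exp(-2 gamma dt)) * sqrt(kT/m)`. SHAKE is applied to positions
#' and a RATTLE projection to velocities at every sub-step. With
#' `tau_friction = Inf` (no thermostat) the scheme reduces to velocity
#' Verlet.
#'
#' @param timestep integration step, ps (default 0.002 with H-bond
#'   constraints)
#' @param temperature target temperature, K (default 300)
#' @param tau_friction friction relaxation time, ps (default 0.4, the
#'   inverse friction constant; `gamma = 1/tau`); `Inf` disables the
#'   thermostat
#' @param seed RNG seed; every random draw in a run derives from it
#' @param n_steps number of steps
#' @param output_stride store a frame every this many steps
#' @param log_stride log energies every this many steps (defaults to
#'   `output_stride`)
#' @param com_removal remove centre-of-mass motion every step (keeps the
#'   system from drifting against the fixed walls)
#' @return an `mmcg_integrator_params` list
#' @export
make_integrator_params <- function(timestep = 0.002, temperature = 300,
                                   tau_friction = 0.4, seed = 1L,
                                   n_steps = 1000L, output_stride = 100L,
                                   log_stride = NULL, com_removal = TRUE) {
  stopifnot(timestep > 0, temperature >= 0, tau_friction > 0,
            n_steps >= 0, output_stride >= 1)
  if (is.null(log_stride)) log_stride <- output_stride
  structure(
    list(timestep = timestep, temperature = temperature,
         tau_friction = tau_friction, seed = as.numeric(seed),
         n_steps = as.integer(n_steps),
         output_stride = as.integer(output_stride),
         log_stride = as.integer(log_stride),
         com_removal = isTRUE(com_removal)),
    class = "mmcg_integrator_params"
  )
}

cpp_params <- function(system, params, step_offset = 0L) {
  nc <- length(system$cpp$con_i)
  n_df <- 3L * system$cpp$n - nc - if (params$com_removal) 3L else 0L
  list(
    dt = params$timestep, temperature = params$temperature,
    gamma = if (is.finite(params$tau_friction)) 1 / params$tau_friction else 0,
    n_steps = params$n_steps, out_stride = params$output_stride,
    log_stride = params$log_stride, seed = params$seed,
    step_offset = as.integer(step_offset),
    com_removal = params$com_removal, n_df = as.integer(n_df),
    save_velocities = isTRUE(params$save_velocities)
  )
}

#' Advance one Langevin step
#'
#' Single-step interface to the integrator, composable into runs: `n`
#' successive calls with the same seed reproduce [run_simulation()] with `n`
#' steps bit for bit (each step draws from its own RNG stream indexed by the
#' step counter).
#'
#' @param system an `mmcg_system`
#' @param state list with `coordinates`, `velocities` (`n x 3`, A and A/ps)
#'   and `step` (integer step counter)
#' @param params `mmcg_integrator_params`
#' @return updated state (coordinates, velocities, step, energy report row)
#' @export
langevin_step <- function(system, state, params) {
  p <- params
  p$n_steps <- 1L
  p$output_stride <- 1L
  p$log_stride <- 1L
  res <- cpp_run(system$cpp, state$coordinates, state$velocities,
                 cpp_params(system, p, step_offset = state$step))
  list(coordinates = res$coords, velocities = res$velocities,
       step = state$step + 1L,
       log = tibble::as_tibble(as.data.frame(res$log))[2, ])
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Deterministic for a given seed; uses the engine's RNG (stream 0) so a run
#' started from these velocities matches a run that initialises internally.
#'
#' @param system an `mmcg_system`
#' @param temperature K
#' @param seed RNG seed
#' @return `n x 3` velocity matrix, A/ps
#' @export
initial_velocities <- function(system, temperature = 300, seed = 1L) {
  n <- system$cpp$n
  g <- matrix(cpp_gaussians(as.numeric(seed), 0, 3L * n), n, 3, byrow = TRUE)
  sd <- sqrt(.kB * temperature * 100 / system$cpp$mass)
  g * sd
}

#' Run a stochastic-dynamics simulation
#'
#' Advances `n_steps` BAOAB Langevin steps at the target temperature with
#' SHAKE/RATTLE constraints, storing a frame every `output_stride` steps
#' (frame 0 included) and logging per-term energies and the instantaneous
#' temperature. Identical system, parameters and seed reproduce the
#' trajectory bit for bit. Velocities are initialised from a
#' Maxwell-Boltzmann draw at the target temperature unless given.
#'
#' @param system an `mmcg_system`
#' @param params `mmcg_integrator_params`
#' @param velocities optional starting velocities (`n x 3`, A/ps)
#' @param replica replica id stored with the frames
#' @return an `mmcg_trajectory`
#' @export
run_simulation <- function(system, params, velocities = NULL, replica = 1L,
                           save_velocities = FALSE) {
  params$save_velocities <- save_velocities
  res <- cpp_run(system$cpp, system$coordinates, velocities,
                 cpp_params(system, params))
  new_trajectory(system$topology, res, params, replica)
}

#' Run independent replicas
#'
#' Replica `k` uses seed `seed + k - 1`; trajectories are returned in
#' replica order ready for [join_replicas()].
#'
#' @inheritParams run_simulation
#' @param n_replicas number of replicas (the production protocol uses 2)
#' @return list of `mmcg_trajectory`
#' @export
run_replicas <- function(system, params, n_replicas = 2L) {
  lapply(seq_len(n_replicas), function(k) {
    p <- params
    p$seed <- params$seed + k - 1
    run_simulation(system, p, replica = k)
  })
}

#' Instantaneous kinetic temperature
#'
#' `T = 2 KE / (kB N_df)` with `N_df = 3 N - N_constraints - 3` when
#' centre-of-mass motion is removed (`- 0` otherwise).
#'
#' @param velocities `n x 3` matrix, A/ps
#' @param masses per-particle masses, amu
#' @param n_constraints number of holonomic constraints
#' @param com_removal whether 3 centre-of-mass degrees of freedom are removed
#' @return temperature, K
#' @export
kinetic_temperature <- function(velocities, masses, n_constraints = 0L,
                                com_removal = FALSE) {
  velocities <- as.matrix(velocities)
  stopifnot(nrow(velocities) == length(masses))
  n_df <- 3L * nrow(velocities) - n_constraints - if (com_removal) 3L else 0L
  if (n_df <= 0) stop("no degrees of freedom left (N_df <= 0)")
  ke <- .ke_conv * 0.5 * sum(masses * rowSums(velocities^2))
  2 * ke / (.kB * n_df)
}


#' Constraint-aware energy minimization
#'
#' Steepest descent with a backtracking line search and a 0.2 A trust
#' radius; after every accepted move the coordinates are projected back
#' onto the SHAKE constraint manifold so rigid water keeps its geometry.
#' Standard practice before starting dynamics: relaxes construction strain
#' so the thermostat does not have to absorb it.
#'
#' @param system an `mmcg_system`
#' @param max_steps iteration cap
#' @param force_tol stop when the largest force component falls below this
#'   (kJ/mol/A)
#' @return the system with minimized coordinates; the final potential
#'   energy and iteration count are attached as attributes
#' @export
minimize_energy <- function(system, max_steps = 500L, force_tol = 10) {
  res <- cpp_minimize(system$cpp, system$coordinates,
                      as.integer(max_steps), force_tol, 0.2)
  system$coordinates <- res$coords
  attr(system, "minimized_energy") <- res$energy
  attr(system, "minimize_iterations") <- res$iterations
  system
}


#' Prepare a system for production dynamics
#'
#' Minimizes the assembled system, refits the Go reference (native C-alpha
#' distances of chain bonds and contacts, and the stored native bead
#' coordinates) to the relaxed structure, and minimizes briefly again. The
#' idealized construction geometry is never exactly the minimum of the full
#' potential; taking the relaxed structure as the native reference removes
#' that systematic strain, exactly as experimental structures are
#' energy-minimized before production runs.
#'
#' @param system an `mmcg_system`
#' @param max_steps minimization iteration cap
#' @param refit_go refit the Go reference distances to the relaxed
#'   structure (default TRUE)
#' @return the prepared system (its `go_model` holds the updated reference)
#' @export
prepare_system <- function(system, max_steps = 500L, refit_go = TRUE) {
  system <- minimize_energy(system, max_steps = max_steps)
  if (refit_go && !is.null(system$go_model)) {
    go <- system$go_model
    ca_sim <- vapply(go$beads$resid, function(r) {
      select_atoms(system$topology, resid = r, name = "CA")[1]
    }, integer(1))
    idx_of <- setNames(ca_sim, go$beads$resid)
    x <- system$coordinates
    if (nrow(go$contacts) > 0) {
      i <- idx_of[as.character(go$contacts$i)]
      j <- idx_of[as.character(go$contacts$j)]
      go$contacts$r_nat <- sqrt(rowSums((x[i, , drop = FALSE] -
                                           x[j, , drop = FALSE])^2))
      system$cpp$goc_r0 <- unname(go$contacts$r_nat)
    }
    if (length(system$cpp$gob_i) > 0) {
      system$cpp$gob_r0 <-
        sqrt(rowSums((x[system$cpp$gob_i, , drop = FALSE] -
                        x[system$cpp$gob_j, , drop = FALSE])^2))
    }
    if (nrow(go$chain_bonds) > 0) {
      i <- idx_of[as.character(go$chain_bonds$i)]
      j <- idx_of[as.character(go$chain_bonds$j)]
      go$chain_bonds$r_nat <- sqrt(rowSums((x[i, , drop = FALSE] -
                                              x[j, , drop = FALSE])^2))
    }
    go$native_ca <- x[ca_sim, , drop = FALSE]
    system$go_model <- go
    system <- minimize_energy(system, max_steps = 100L)
  }
  system
}
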