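# Assembly of the flat argument list consumed by the compiled engine, plus
# the EnergyReport wrapper and the standalone per-term evaluators.

cpp_sys_skeleton <- function(n, mass) {
  list(
    n = as.integer(n),
    mass = as.numeric(mass),
    charge = numeric(n),
    sigma = rep(1.0, n),
    eps = numeric(n),
    is_bead = integer(n),
    is_gonode = integer(n),
    is_h = integer(n),
    excl_i = integer(0), excl_j = integer(0),
    p14_i = integer(0), p14_j = integer(0),
    scale14_lj = 1.0, scale14_coul = 1.0,
    bond_i = integer(0), bond_j = integer(0),
    bond_k = numeric(0), bond_r0 = numeric(0),
    ang_i = integer(0), ang_j = integer(0), ang_k = integer(0),
    ang_kth = numeric(0), ang_th0 = numeric(0),
    dih_i = integer(0), dih_j = integer(0), dih_k = integer(0),
    dih_l = integer(0), dih_kd = numeric(0), dih_n = integer(0),
    dih_phase = numeric(0),
    gob_i = integer(0), gob_j = integer(0),
    gob_r0 = numeric(0), gob_k = numeric(0),
    goc_i = integer(0), goc_j = integer(0),
    goc_r0 = numeric(0), goc_eps = numeric(0),
    skip_i = integer(0), skip_j = integer(0),
    sigma_rep = 4.0, eps_rep = 0.0,
    r_cut = 16.0, shift = TRUE,
    walls = list(enabled = FALSE),
    con_i = integer(0), con_j = integer(0), con_d0 = numeric(0),
    con_tol = 1e-4, con_maxit = 500L
  )
}

energy_report <- function(raw) {
  stopifnot(abs(raw$total - sum(raw$terms)) <=
              1e-9 * max(1, abs(raw$total)))
  structure(list(terms = raw$terms, total = raw$total, forces = raw$forces),
            class = "mmcg_energy_report")
}

#' @export
print.mmcg_energy_report <- function(x, ...) {
  cat("mmcg energy report (kJ/mol):\n")
  nz <- x$terms[x$terms != 0 | names(x$terms) %in% c("lj", "coulomb")]
  for (nm in names(nz)) cat(sprintf("  %-10s %14.6f\n", nm, nz[[nm]]))
  cat(sprintf("  %-10s %14.6f\n", "total", x$total))
  invisible(x)
}

#' Serialize an energy report to delimited text
#' @param report an `mmcg_energy_report`
#' @param path output file (tab-separated `term`, `energy` rows plus total)
#' @export
write_energy_report <- function(report, path) {
  df <- data.frame(term = c(names(report$terms), "total"),
                   energy = c(unname(report$terms), report$total))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tidy an energy report into a tibble
#' @param x an `mmcg_energy_report`
#' @param ... unused
#' @export
tidy.mmcg_energy_report <- function(x, ...) {
  tibble::tibble(term = names(x$terms), energy = unname(x$terms))
}

#' Bonded MM energy and forces (bonds, angles, dihedrals)
#'
#' Harmonic bonds `k/2 (r - r0)^2`, harmonic angles `k/2 (theta - theta0)^2`
#' and periodic dihedrals `k (1 + cos(n phi - delta))`, with parameters
#' looked up by atom type. Forces are the exact analytic negative gradient.
#'
#' @param topology an `mmcg_topology` (atomistic)
#' @param coordinates `n x 3` matrix, Angstrom
#' @param parameters an `mmcg_parameters` set
#' @return an `mmcg_energy_report`
#' @export
mm_bonded_energy_forces <- function(topology, coordinates, parameters) {
  coordinates <- check_coords(topology, coordinates)
  bt <- build_bonded_terms(topology, parameters)
  sys <- cpp_sys_skeleton(n_atoms(topology), topology$atoms$mass)
  sys$bond_i <- bt$bonds$i; sys$bond_j <- bt$bonds$j
  sys$bond_k <- bt$bonds$k; sys$bond_r0 <- bt$bonds$r0
  sys$ang_i <- bt$angles$i; sys$ang_j <- bt$angles$j; sys$ang_k <- bt$angles$k
  sys$ang_kth <- bt$angles$kth; sys$ang_th0 <- bt$angles$th0
  sys$dih_i <- bt$dihedrals$i; sys$dih_j <- bt$dihedrals$j
  sys$dih_k <- bt$dihedrals$k; sys$dih_l <- bt$dihedrals$l
  sys$dih_kd <- bt$dihedrals$kd; sys$dih_n <- bt$dihedrals$n
  sys$dih_phase <- bt$dihedrals$phase
  energy_report(cpp_energy_forces(sys, coordinates))
}

#' Nonbonded MM energy and forces (12-6 LJ + Coulomb)
#'
#' Pairwise Lennard-Jones and Coulomb interactions within the cutoff,
#' truncated and energy-shifted so each pair energy is continuous (zero) at
#' `r_cut`. 1-2 and 1-3 pairs are excluded; 1-4 pairs are scaled per the
#' parameter options (full strength by default). The Coulomb constant is
#' 1389.35458 kJ mol-1 A e-2 with dielectric 1 (explicit water carries the
#' screening).
#'
#' @inheritParams mm_bonded_energy_forces
#' @param shift energy-shift pair terms to zero at the cutoff (default TRUE)
#' @return an `mmcg_energy_report`
#' @export
mm_nonbonded_energy_forces <- function(topology, coordinates, parameters,
                                       shift = TRUE) {
  coordinates <- check_coords(topology, coordinates)
  bt <- build_bonded_terms(topology, parameters)
  sys <- cpp_sys_skeleton(n_atoms(topology), topology$atoms$mass)
  sys$charge <- bt$atom_params$charge
  sys$sigma <- bt$atom_params$sigma
  sys$eps <- bt$atom_params$eps
  sys$excl_i <- c(bt$excl$i, bt$p14$i)
  sys$excl_j <- c(bt$excl$j, bt$p14$j)
  sys$p14_i <- bt$p14$i; sys$p14_j <- bt$p14$j
  sys$scale14_lj <- parameters$options$scale14_lj
  sys$scale14_coul <- parameters$options$scale14_coul
  sys$r_cut <- parameters$options$r_cut
  sys$shift <- shift
  energy_report(cpp_energy_forces(sys, coordinates))
}
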