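# ggplot2 figure helpers for the analysis outputs (ggplot2 is optional).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
}

#' Plot a C-alpha RMSD time series
#' @param rmsd tibble from [rmsd_timeseries()]
#' @return a ggplot object
#' @export
plot_rmsd <- function(rmsd) {
  need_ggplot()
  ggplot2::ggplot(rmsd, ggplot2::aes(x = time, y = rmsd,
                                     colour = factor(replica))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = expression(C[alpha] ~ RMSD ~ (ring(A))),
                  colour = "replica") +
    ggplot2::theme_minimal()
}

#' Plot donor-acceptor distance distributions
#' @param series tibble from [hbond_series()]
#' @param binwidth histogram bin width, Angstrom
#' @return a ggplot object
#' @export
plot_hbond_distances <- function(series, binwidth = 0.1) {
  need_ggplot()
  ggplot2::ggplot(series, ggplot2::aes(x = distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = NA) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "donor-acceptor distance (Å)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot the energy log of a run
#' @param trajectory an `mmcg_trajectory` with an energy log
#' @return a ggplot object
#' @export
plot_energy_log <- function(trajectory) {
  need_ggplot()
  log <- trajectory$energy_log
  if (is.null(log)) stop("trajectory has no energy log")
  df <- data.frame(
    time = rep(log$time, 3),
    energy = c(log$potential, log$kinetic, log$total),
    term = rep(c("potential", "kinetic", "total"), each = nrow(log))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = energy,
                                   colour = term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "energy (kJ/mol)") +
    ggplot2::theme_minimal()
}
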