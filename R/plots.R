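#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_step
#'   geom_histogram geom_col labs facet_wrap scale_x_log10 after_stat
#' @export
ggplot2::autoplot

#' Plot a kinetic fit
#'
#' Dispatches on the fit's model: the cumulative fraction-bound curve
#' with its exponential fit, a dwell-time histogram with the fitted decay,
#' a FRET-change histogram with the fitted Gaussian, or a dose-response
#' curve with the fitted isotherm.
#'
#' @param object A `kin_fit`.
#' @param bins Histogram bins for the dwell/Gaussian panels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_fit
#' @export
autoplot.kin_fit <- function(object, bins = 30, ...) {
  est <- function(term) {
    object$estimates$estimate[object$estimates$term == term]
  }
  switch(object$model,
    "binding-cdf" = {
      ggplot(object$data, aes(x = .data$t)) +
        geom_step(aes(y = .data$fraction_bound)) +
        geom_line(aes(y = .data$fitted), color = "firebrick") +
        labs(x = "time (s)", y = "cumulative fraction bound",
             title = sprintf("k_obs = %.3g /s, %.0f%% bound",
                             est("k_obs"), 100 * est("bound_fraction")))
    },
    "dwell-exp" = {
      tau <- est("tau")
      cutoff <- object$extra$cutoff %||% 0
      grid <- seq(cutoff, max(object$data$duration_s), length.out = 100)
      dens <- tibble::tibble(t = grid, y = exp(-(grid - cutoff) / tau) / tau)
      ggplot(object$data, aes(x = .data$duration_s)) +
        geom_histogram(aes(y = after_stat(density)), bins = bins,
                       fill = "grey70", color = "white") +
        geom_line(data = dens, aes(x = .data$t, y = .data$y),
                  color = "firebrick") +
        labs(x = "dwell time (s)", y = "probability density",
             title = sprintf("tau = %.2f s (n = %d)", tau, object$n_obs))
    },
    "gaussian" = {
      mu <- est("mu"); sigma <- est("sigma")
      grid <- seq(min(object$data$delta_e), max(object$data$delta_e),
                  length.out = 100)
      dens <- tibble::tibble(x = grid,
                             y = stats::dnorm(grid, mu, max(sigma, 1e-6)))
      ggplot(object$data, aes(x = .data$delta_e)) +
        geom_histogram(aes(y = after_stat(density)), bins = bins,
                       fill = "grey70", color = "white") +
        geom_line(data = dens, aes(x = .data$x, y = .data$y),
                  color = "firebrick") +
        labs(x = "FRET change magnitude", y = "probability density",
             title = sprintf("mu = %.3f, sigma = %.3f", mu, sigma))
    },
    "isotherm" = {
      ggplot(object$data, aes(x = .data$ligand)) +
        geom_point(aes(y = .data$response)) +
        geom_line(aes(y = .data$fitted), color = "firebrick") +
        scale_x_log10() +
        labs(x = "ligand (M)", y = "response",
             title = sprintf("K_D = %.3g M", est("kd")))
    },
    stop_invalid(paste0("no plot for model ", object$model)))
}

#' Plot a three-channel trajectory
#'
#' @param traj Trajectory tibble.
#' @param molecules Molecule ids to show (default first 4).
#' @return A ggplot object with one panel per molecule, channels colored.
#' @export
plot_trajectory <- function(traj, molecules = NULL) {
  if (is.null(molecules)) molecules <- utils::head(unique(traj$molecule_id), 4)
  df <- dplyr::filter(traj, .data$molecule_id %in% molecules)
  long <- tidyr::pivot_longer(df, c("F_DD", "F_DA", "F_AA"),
                              names_to = "channel", values_to = "photons")
  ggplot(long, aes(x = .data$time_s, y = .data$photons,
                   color = .data$channel)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~molecule_id, ncol = 1) +
    labs(x = "time (s)", y = "photons / frame")
}

#' Plot corrected FRET efficiency with called events
#'
#' @param trace Corrected trace from [compute_efret()].
#' @param events Optional events from [call_fret_events()] to shade.
#' @param molecules Molecule ids to show (default first 4).
#' @return A ggplot object.
#' @export
plot_efret <- function(trace, events = NULL, molecules = NULL) {
  if (is.null(molecules)) molecules <- utils::head(unique(trace$molecule_id), 4)
  df <- dplyr::filter(trace, .data$molecule_id %in% molecules, .data$valid)
  p <- ggplot(df, aes(x = .data$time_s, y = .data$E)) +
    geom_line(linewidth = 0.3, color = "grey40") +
    facet_wrap(~molecule_id, ncol = 1) +
    labs(x = "time (s)", y = expression(E[FRET]))
  if (!is.null(events) && nrow(events) > 0) {
    ev <- dplyr::filter(events, .data$molecule_id %in% molecules)
    if (nrow(ev) > 0) {
      p <- p + ggplot2::geom_rect(
        data = ev,
        aes(xmin = .data$start_s, xmax = .data$end_s),
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
        inherit.aes = FALSE)
    }
  }
  p
}
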