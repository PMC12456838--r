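#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for hetnetdyn objects
#'
#' `autoplot()` methods returning ggplot objects: activity traces for
#' trajectories, the population-mean PSD for spectra, the complex-plane
#' eigenvalue cloud, the order-parameter heat map with the analytic
#' transition curve, and the per-delay memory function.
#'
#' @param object A hetnetdyn result object.
#' @param neurons Neuron indices to draw (trajectories).
#' @param ... Unused.
#' @return A `ggplot`.
#' @name hetnetdyn-autoplot
NULL

#' @rdname hetnetdyn-autoplot
#' @method autoplot trajectory
#' @export
autoplot.trajectory <- function(object, neurons = seq_len(min(8, ncol(object$x))),
                                ...) {
  df <- as_tibble.trajectory(object, neurons = neurons)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$x,
                                   colour = factor(.data$neuron))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time", y = "activity x", colour = "neuron") +
    ggplot2::theme_minimal()
}

#' @rdname hetnetdyn-autoplot
#' @method autoplot spectrum_estimate
#' @export
autoplot.spectrum_estimate <- function(object, ...) {
  df <- as_tibble.spectrum_estimate(object)
  ggplot2::ggplot(df[df$omega > 0, ],
                  ggplot2::aes(.data$omega, .data$psd_mean)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(omega), y = "mean PSD") +
    ggplot2::theme_minimal()
}

#' @rdname hetnetdyn-autoplot
#' @method autoplot eigen_spectrum
#' @export
autoplot.eigen_spectrum <- function(object, ...) {
  df <- as_tibble.eigen_spectrum(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$re, .data$im,
                                   colour = .data$re > 0)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Re", y = "Im") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @rdname hetnetdyn-autoplot
#' @method autoplot phase_diagram
#' @export
autoplot.phase_diagram <- function(object, ...) {
  gc_df <- dplyr::distinct(object, .data$het, .data$gc_analytic)
  ggplot2::ggplot(object, ggplot2::aes(.data$het, .data$g)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(pmax(.data$order_parameter,
                                                      1e-12)))) +
    ggplot2::geom_line(data = gc_df,
                       ggplot2::aes(.data$het, .data$gc_analytic),
                       colour = "red", linewidth = 1) +
    ggplot2::scale_fill_viridis_c(name = "log10 max PSD") +
    ggplot2::labs(x = "heterogeneity", y = "g") +
    ggplot2::theme_minimal()
}

#' @rdname hetnetdyn-autoplot
#' @method autoplot memory_capacity
#' @export
autoplot.memory_capacity <- function(object, ...) {
  df <- tidy.memory_capacity(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$delay, .data$mc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "delay (time units)", y = "squared correlation") +
    ggplot2::theme_minimal()
}
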