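#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidiers for hetnetdyn result objects
#'
#' Broom-style one-row-per-quantity summaries. `tidy()` gives the detailed
#' table; `glance()` a one-row overview.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name hetnetdyn-tidiers
NULL

#' @rdname hetnetdyn-tidiers
#' @method tidy critical_coupling
#' @export
tidy.critical_coupling <- function(x, ...) {
  tibble::tibble(gc = x$gc, omega_star = x$omega_star,
                 gain_max = x$gain_max, method = x$method)
}

#' @rdname hetnetdyn-tidiers
#' @method tidy lyapunov_estimate
#' @export
tidy.lyapunov_estimate <- function(x, ...) {
  tibble::tibble(realization = seq_along(x$lambda), lambda = x$lambda)
}

#' @rdname hetnetdyn-tidiers
#' @method glance lyapunov_estimate
#' @export
glance.lyapunov_estimate <- function(x, ...) {
  tibble::tibble(lambda_max = x$lambda_max, std = x$std,
                 n_init = length(x$lambda),
                 T_measure = x$settings$T_measure,
                 renorm_interval = x$settings$renorm_interval)
}

#' @rdname hetnetdyn-tidiers
#' @method tidy memory_capacity
#' @export
tidy.memory_capacity <- function(x, ...) {
  tibble::tibble(delay = x$delays, mc = x$mc_per_delay, flagged = x$flags)
}

#' @rdname hetnetdyn-tidiers
#' @method glance memory_capacity
#' @export
glance.memory_capacity <- function(x, ...) {
  tibble::tibble(mc_total = x$mc_total, n_delays = length(x$delays),
                 sigma_in = x$settings$sigma_in,
                 n_train = x$settings$n_train, n_test = x$settings$n_test)
}

#' @rdname hetnetdyn-tidiers
#' @method tidy eigen_spectrum
#' @export
tidy.eigen_spectrum <- function(x, ...) as_tibble.eigen_spectrum(x)

#' @rdname hetnetdyn-tidiers
#' @method glance eigen_spectrum
#' @export
glance.eigen_spectrum <- function(x, ...) {
  tibble::tibble(spectral_abscissa = x$spectral_abscissa,
                 n_eigenvalues = length(x$eigenvalues),
                 N = x$model_ref$N, g = x$model_ref$g)
}

#' @rdname hetnetdyn-tidiers
#' @method tidy spectrum_estimate
#' @export
tidy.spectrum_estimate <- function(x, ...) as_tibble.spectrum_estimate(x)

#' @rdname hetnetdyn-tidiers
#' @method glance spectrum_estimate
#' @export
glance.spectrum_estimate <- function(x, ...) {
  tibble::tibble(max_power = x$max_power, n_bins = length(x$omega),
                 n_segments = x$settings$n_segments)
}
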