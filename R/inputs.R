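#' Input protocols for network simulations
#'
#' * `input_none()` — autonomous dynamics, `I_i(t) = 0`.
#' * `input_pulse_train(events, targets)` — piecewise-constant pulses.
#'   `events` is a data frame with columns `t_start`, `t_end`, `amplitude`;
#'   `targets` is `"all"` or an integer vector of neuron indices. Pulse
#'   intervals must not overlap (per target set).
#' * `input_white_noise(sigma_in, weights)` — a single shared Gaussian
#'   white-noise signal `u` entering through per-neuron `weights`; each
#'   Euler step adds `weights * u_n` with `u_n ~ N(0, sigma_in^2 * dt)`
#'   (Euler-Maruyama).
#'
#' @param events Data frame of pulses (`t_start`, `t_end`, `amplitude`).
#' @param targets `"all"` or integer neuron indices.
#' @param sigma_in Noise amplitude scale, `>= 0`.
#' @param weights Per-neuron input weights (recycled to N at integration).
#' @return An `input_protocol` object.
#' @export
input_none <- function() {
  structure(list(kind = "none"), class = "input_protocol")
}

#' @rdname input_none
#' @export
input_pulse_train <- function(events, targets = "all") {
  events <- as.data.frame(events)
  need <- c("t_start", "t_end", "amplitude")
  if (!all(need %in% names(events))) {
    abort_param("`events` needs columns t_start, t_end, amplitude.")
  }
  if (nrow(events) > 0) {
    if (any(events$t_end <= events$t_start)) {
      abort_param("each pulse needs t_end > t_start.")
    }
    ev <- events[order(events$t_start), ]
    if (nrow(ev) > 1 && any(ev$t_start[-1] < ev$t_end[-nrow(ev)])) {
      abort_param("pulse intervals must not overlap.")
    }
  }
  if (!identical(targets, "all")) targets <- as.integer(targets)
  structure(list(kind = "pulse_train", events = events, targets = targets),
            class = "input_protocol")
}

#' @rdname input_none
#' @export
input_white_noise <- function(sigma_in, weights = 1) {
  if (!is.numeric(sigma_in) || sigma_in < 0) abort_param("`sigma_in` must be >= 0.")
  structure(list(kind = "shared_white_noise", sigma_in = sigma_in,
                 weights = weights),
            class = "input_protocol")
}

#' @export
print.input_protocol <- function(x, ...) {
  cat(sprintf("<input_protocol: %s>\n", x$kind))
  invisible(x)
}

# Deterministic input vector at time t for N neurons (pulse trains / none).
input_at <- function(input, t, N) {
  if (input$kind != "pulse_train" || nrow(input$events) == 0) return(NULL)
  amp <- 0
  ev <- input$events
  on <- t >= ev$t_start & t < ev$t_end
  if (!any(on)) return(NULL)
  amp <- sum(ev$amplitude[on])
  I <- numeric(N)
  if (identical(input$targets, "all")) I[] <- amp else I[input$targets] <- amp
  I
}
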