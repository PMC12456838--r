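#' Integrate the network dynamics
#'
#' Fixed-step explicit Euler integration of
#' \deqn{\dot x_i = -x_i + a_i + \sum_j J_{ij}\phi(x_j) + I_i(t), \qquad
#'       \dot a_i = -\gamma_i a_i + \beta_i x_i,}
#' switching to Euler-Maruyama when the input protocol is shared white
#' noise (the stochastic increment `weights * u_n`, `u_n ~ N(0,
#' sigma_in^2 dt)`, is added once per step, not multiplied by `dt`).
#'
#' The trajectory records the state *after* each step at times
#' `t0 + dt, ..., t0 + T_total`; the initial condition is not stored.
#' Any `|x|` or `|a|` exceeding `guard` (default `1e6`), or a non-finite
#' value, aborts with a divergence error carrying the first bad step.
#'
#' @param model A [network_model][build_network].
#' @param input An [input_protocol][input_none]; default no input.
#' @param x0,a0 Initial states (length N); default zeros.
#' @param dt Time step (> 0); default `0.02`.
#' @param T_total Total integration time.
#' @param seed Optional seed for the noise path (pure function of it).
#' @param t0 Start time (pulse event times are absolute).
#' @param record `"xa"` (default) stores both variables, `"x"` stores only
#'   the activity (halves memory for spectral diagnostics).
#' @param guard Divergence guard on `max(abs(state))`.
#' @return A `trajectory`: list with `t0`, `dt`, `times`, matrices `x` (and
#'   `a`), the shared-noise series `u` (white-noise input only), and model
#'   provenance in `model_ref`.
#' @export
integrate_network <- function(model, input = input_none(), x0 = NULL, a0 = NULL,
                              dt = 0.02, T_total, seed = NULL, t0 = 0,
                              record = c("xa", "x"), guard = 1e6) {
  stopifnot(inherits(model, "network_model"), inherits(input, "input_protocol"))
  record <- match.arg(record)
  if (!is.numeric(dt) || dt <= 0) abort_param("`dt` must be > 0.")
  pop <- model$population
  N <- pop$N
  J <- model$coupling$J
  gamma <- pop$gamma
  beta <- pop$beta
  act <- activation_fn(pop$activation)
  if (is.null(x0)) x0 <- numeric(N)
  if (is.null(a0)) a0 <- numeric(N)
  if (length(x0) != N || length(a0) != N) {
    abort_param("`x0` and `a0` must have length N.")
  }
  steps <- max(1L, as.integer(round(T_total / dt)))

  noisy <- input$kind == "shared_white_noise"
  u <- NULL
  w <- NULL
  if (noisy) {
    u <- with_rng(seed, stats::rnorm(steps, sd = input$sigma_in * sqrt(dt)))
    w <- rep_len(input$weights, N)
  }

  xm <- matrix(NA_real_, steps, N)
  am <- if (record == "xa") matrix(NA_real_, steps, N) else NULL
  x <- as.numeric(x0)
  a <- as.numeric(a0)
  zeroJ <- model$coupling$g == 0
  pulsed <- input$kind == "pulse_train"
  for (n in seq_len(steps)) {
    t <- t0 + (n - 1) * dt
    drift <- -x + a
    if (!zeroJ) drift <- drift + as.vector(J %*% act$phi(x))
    if (pulsed) {
      Idet <- input_at(input, t, N)
      if (!is.null(Idet)) drift <- drift + Idet
    }
    anew <- a + dt * (-gamma * a + beta * x)
    x <- x + dt * drift
    if (noisy) x <- x + w * u[n]
    a <- anew
    xm[n, ] <- x
    if (!is.null(am)) am[n, ] <- a
    if (n %% 50L == 0L || n == steps) {
      m <- max(abs(x), abs(a))
      if (!is.finite(m) || m > guard) {
        rlang::abort(
          sprintf("state diverged (|state| > %g or non-finite) at step %d (t = %.4g)",
                  guard, n, t + dt),
          class = "hetnetdyn_divergence_error", step = n
        )
      }
    }
  }

  structure(
    list(
      t0 = t0, dt = dt, times = t0 + dt * seq_len(steps),
      x = xm, a = am, u = u,
      model_ref = list(N = N, g = model$coupling$g, seed = model$metadata$seed,
                       activation = pop$activation)
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d steps x %d neurons, dt = %g, t in (%g, %g]>\n",
              nrow(x$x), ncol(x$x), x$dt, x$t0, max(x$times)))
  invisible(x)
}

#' Tidy a trajectory into long format
#'
#' @param x A [trajectory][integrate_network].
#' @param neurons Integer indices of neurons to keep (default: all).
#' @param ... Unused.
#' @return A tibble with columns `time`, `neuron`, `x` and (when recorded) `a`.
#' @method as_tibble trajectory
#' @export
as_tibble.trajectory <- function(x, neurons = seq_len(ncol(x$x)), ...) {
  out <- tibble::tibble(
    time = rep(x$times, length(neurons)),
    neuron = rep(neurons, each = length(x$times)),
    x = as.vector(x$x[, neurons, drop = FALSE])
  )
  if (!is.null(x$a)) out$a <- as.vector(x$a[, neurons, drop = FALSE])
  out
}

#' Simulate a single isolated neuron under a pulse protocol
#'
#' Convenience wrapper around [integrate_network()] with `N = 1`, `g = 0`.
#' With `gamma` slightly above `beta` the neuron shows graded persistent
#' activity: a plateau that steps up after depolarizing pulses and down
#' after hyperpolarizing ones. With large `gamma` the activity decays
#' rapidly at pulse offset.
#'
#' @param gamma,beta Intrinsic parameters of the neuron (a warning is issued
#'   when `gamma <= beta`, where the linear dynamics diverge).
#' @param pulses Data frame of pulses (`t_start`, `t_end`, `amplitude`).
#' @param dt,T_total Integration settings.
#' @param x0,a0 Initial state (scalars).
#' @return A [trajectory][integrate_network] with one neuron.
#' @export
#' @examples
#' pulses <- data.frame(t_start = c(5, 20), t_end = c(6, 21), amplitude = 1)
#' tr <- single_neuron_pulse_response(gamma = 0.51, beta = 0.5, pulses,
#'                                    T_total = 40)
single_neuron_pulse_response <- function(gamma, beta, pulses, dt = 0.02,
                                         T_total, x0 = 0, a0 = 0) {
  if (gamma <= beta) {
    rlang::warn("gamma <= beta: the uncoupled linear neuron diverges.")
  }
  model <- build_network(dist_constant(gamma), dist_constant(beta),
                         N = 1, g = 0, seed = 0, allow_unstable = TRUE)
  integrate_network(model, input_pulse_train(pulses), x0 = x0, a0 = a0,
                    dt = dt, T_total = T_total)
}

#' Per-neuron response amplitudes to a shared transient impulse
#'
#' Applies one shared pulse to every neuron of a (recommended subcritical)
#' network and records each neuron's peak absolute activity after pulse
#' onset. In heterogeneous networks the post-pulse decay time grows with
#' the feedback strength `beta_i`, so the profile is sortable by `beta`.
#'
#' @param model A [network_model][build_network].
#' @param amplitude,t_on,duration Pulse amplitude, onset time and duration.
#' @param dt,T_total Integration settings (`T_total` measured from 0).
#' @param x0,a0 Optional initial state (defaults: rest at the origin).
#' @return An `impulse_profile`: tibble with columns `neuron`, `gamma`,
#'   `beta`, `amplitude` (peak `|x|` after onset), `decay_time` (time after
#'   pulse offset for `|x|` to fall below 10% of the peak; `NA` if never).
#' @export
impulse_response_experiment <- function(model, amplitude = 1, t_on = 5,
                                        duration = 0.5, dt = 0.02,
                                        T_total = NULL, x0 = NULL, a0 = NULL) {
  if (is.null(T_total)) T_total <- t_on + duration + 45
  pulses <- data.frame(t_start = t_on, t_end = t_on + duration,
                       amplitude = amplitude)
  tr <- integrate_network(model, input_pulse_train(pulses), x0 = x0, a0 = a0,
                          dt = dt, T_total = T_total)
  post <- tr$times >= t_on
  xa <- abs(tr$x[post, , drop = FALSE])
  peak <- apply(xa, 2, max)
  off <- tr$times >= t_on + duration
  xoff <- abs(tr$x[off, , drop = FALSE])
  toff <- tr$times[off]
  decay_time <- vapply(seq_len(ncol(xoff)), function(i) {
    if (peak[i] == 0) return(0)
    k <- which(xoff[, i] < 0.1 * peak[i])[1]
    if (is.na(k)) NA_real_ else toff[k] - (t_on + duration)
  }, numeric(1))
  out <- tibble::tibble(
    neuron = seq_along(peak),
    gamma = model$population$gamma,
    beta = model$population$beta,
    amplitude = peak,
    decay_time = decay_time
  )
  class(out) <- c("impulse_profile", class(out))
  out
}
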