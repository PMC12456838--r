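#' Welch power spectral density of multichannel series
#'
#' Hann-windowed, overlapping-segment averaged periodograms, column-wise.
#' Densities are reported against *angular* frequency `omega` (rad per time
#' unit) and normalised so that the one-sided integral recovers the series
#' variance: `sum(psd) * d_omega ~ var(x)` (Parseval, up to windowing
#' bias).
#'
#' @param x Numeric matrix (time by channels) or vector.
#' @param dt Sampling interval.
#' @param nfft Segment length in samples (default `2^10`).
#' @param overlap Fractional segment overlap (default `0.5`).
#' @param demean Remove each segment's mean before windowing.
#' @return List with `omega` (length `nfft/2 + 1`) and `psd` (frequency by
#'   channel matrix).
#' @keywords internal
psd_welch <- function(x, dt, nfft = 1024, overlap = 0.5, demean = TRUE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  Tn <- nrow(x)
  nfft <- as.integer(nfft)
  if (Tn < nfft) {
    rlang::abort(
      sprintf("series too short for spectral estimation: %d samples < segment length %d",
              Tn, nfft),
      class = "hetnetdyn_length_error"
    )
  }
  step <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq(1L, Tn - nfft + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft) # Hann
  wnorm <- sum(win^2)
  nf <- nfft %/% 2 + 1L
  acc <- matrix(0, nf, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L), , drop = FALSE]
    if (demean) seg <- sweep(seg, 2, colMeans(seg))
    seg <- seg * win
    ft <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
    p <- (Mod(ft)^2) * (dt / wnorm)
    # one-sided: double interior bins
    if (nf > 2) p[2:(nf - 1L), ] <- 2 * p[2:(nf - 1L), ]
    acc <- acc + p
  }
  psd_f <- acc / length(starts) # density per cyclic frequency
  freqs <- (seq_len(nf) - 1L) / (nfft * dt)
  list(omega = 2 * pi * freqs, psd = psd_f / (2 * pi), n_segments = length(starts))
}

#' Estimate per-neuron and population-mean power spectral densities
#'
#' Welch estimate (Hann window, 50% overlap) of the activity spectra of a
#' trajectory, optionally after applying the activation function
#' (`on_phi = TRUE` gives the spectra of `phi(x)`, whose population mean
#' scaled by `g^2` is the mean-field input spectrum `S_H`). Each neuron's
#' series is mean-removed.
#'
#' @param traj A [trajectory][integrate_network].
#' @param on_phi Estimate spectra of `phi(x)` instead of `x`.
#' @param nfft,overlap Welch settings (segment length in samples, fractional
#'   overlap).
#' @param t_min,t_max Keep only samples with `t_min <= time < t_max`
#'   (transient removal / windowing).
#' @param per_neuron Keep the N-column matrix of per-neuron densities.
#' @param demean Remove each segment's mean before windowing (default). The
#'   raw (`demean = FALSE`) spectrum retains the DC component and is the
#'   estimator matching the definition `S_x = F[<x(t+tau) x(t)>]`, under
#'   which a frozen nonzero state still carries zero-frequency power.
#' @return A `spectrum_estimate`: fields `omega`, `psd_mean`,
#'   `psd_per_neuron` (optional), `max_power = max(psd_mean)`, `settings`.
#' @export
estimate_psd <- function(traj, on_phi = FALSE, nfft = 1024, overlap = 0.5,
                         t_min = NULL, t_max = NULL, per_neuron = FALSE,
                         demean = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  keep <- rep(TRUE, nrow(traj$x))
  if (!is.null(t_min)) keep <- keep & traj$times >= t_min
  if (!is.null(t_max)) keep <- keep & traj$times < t_max
  x <- traj$x[keep, , drop = FALSE]
  if (on_phi) {
    act <- activation_fn(traj$model_ref$activation)
    x <- act$phi(x)
  }
  w <- psd_welch(x, traj$dt, nfft = nfft, overlap = overlap, demean = demean)
  structure(
    list(
      omega = w$omega,
      psd_mean = rowMeans(w$psd),
      psd_per_neuron = if (per_neuron) w$psd else NULL,
      max_power = max(rowMeans(w$psd)),
      settings = list(nfft = nfft, overlap = overlap, window = "hann",
                      on_phi = on_phi, demean = demean,
                      n_segments = w$n_segments, dt = traj$dt)
    ),
    class = "spectrum_estimate"
  )
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate: %d bins, max power %.4g (%d segments)>\n",
              length(x$omega), x$max_power, x$settings$n_segments))
  invisible(x)
}

#' @method as_tibble spectrum_estimate
#' @export
as_tibble.spectrum_estimate <- function(x, ...) {
  tibble::tibble(omega = x$omega, psd_mean = x$psd_mean)
}

#' Max-power order parameter of a free-running network
#'
#' Simulates the autonomous network from random initial activity
#' (`x(0) ~ N(0,1)`, `a(0) = 0`), discards a transient, and returns the
#' maximum over frequency of the population-mean activity PSD of the raw
#' (not mean-removed) series, i.e. the estimator of
#' `max_omega mean_i F[<x_i(t+tau) x_i(t)>]`. The raw spectrum matters:
#' above the transition these networks can settle on frozen *nonzero*
#' states whose power sits entirely at zero frequency. The PSD is
#' nonnegative, so a maximum above the numerical floor (see
#' [silent_threshold()]) indicates escape from the quiescent state; in the
#' silent phase the trajectory decays to the origin and the order parameter
#' is essentially zero.
#'
#' @param model A [network_model][build_network].
#' @param T_run Post-transient measurement duration (time units).
#' @param T_trans Discarded transient duration.
#' @param dt Integration step.
#' @param seed Seed for the initial condition (`"init"` stream of it).
#' @param nfft,overlap Welch settings.
#' @return A single nonnegative number (units of activity PSD).
#' @export
max_power_order_parameter <- function(model, T_run = 500, T_trans = 50,
                                      dt = 0.02, seed = 1, nfft = 1024,
                                      overlap = 0.5) {
  tr <- free_run(model, T_run, T_trans, dt, seed)
  estimate_psd(tr, t_min = T_trans, nfft = nfft, overlap = overlap,
               demean = FALSE)$max_power
}

# Order parameter on the first and final halves of the measurement window,
# from one simulation. A cell is "dynamic" when the final-half order
# parameter is above the silent threshold AND has not kept decaying
# relative to the first half (stationarity); a decaying transient shrinks
# across the window, whereas chaos or a frozen nonzero state does not.
op_two_windows <- function(model, T_run, T_trans, dt, seed, nfft, overlap = 0.5) {
  tr <- free_run(model, T_run, T_trans, dt, seed)
  mid <- T_trans + T_run / 2
  nfft_h <- min(nfft, 2^floor(log2(T_run / 2 / dt)))
  op1 <- estimate_psd(tr, t_min = T_trans, t_max = mid, nfft = nfft_h,
                      overlap = overlap, demean = FALSE)$max_power
  op2 <- estimate_psd(tr, t_min = mid, nfft = nfft_h, overlap = overlap,
                      demean = FALSE)$max_power
  op <- estimate_psd(tr, t_min = T_trans, nfft = min(nfft, nfft_h * 2),
                     overlap = overlap, demean = FALSE)$max_power
  list(op = op, first = op1, final = op2)
}

free_run <- function(model, T_run, T_trans, dt, seed) {
  N <- model$population$N
  x0 <- with_rng(sub_seed(seed, "init"), stats::rnorm(N))
  integrate_network(model, input_none(), x0 = x0, a0 = numeric(N),
                    dt = dt, T_total = T_trans + T_run, record = "x")
}

#' Numerical silent-phase threshold for the order parameter
#'
#' Runs the identical free-run pipeline on a matched uncoupled (`g = 0`)
#' copy of the model and returns 5 times the maximum PSD of the final
#' quarter of its post-transient trajectory — a pure numerical floor below
#' which a network is classified as silent. A small absolute floor guards
#' against exact underflow to zero.
#'
#' @inheritParams max_power_order_parameter
#' @return A positive threshold on the same scale as the order parameter.
#' @export
silent_threshold <- function(model, T_run = 500, T_trans = 50, dt = 0.02,
                             seed = 1, nfft = 1024, overlap = 0.5) {
  ref <- model
  ref$coupling$J <- matrix(0, model$population$N, model$population$N)
  ref$coupling$g <- 0
  tr <- free_run(ref, T_run, T_trans, dt, seed)
  tq <- T_trans + 0.75 * T_run
  nfft_q <- min(nfft, 2^floor(log2(sum(tr$times >= tq))))
  sp <- estimate_psd(tr, t_min = tq, nfft = nfft_q, overlap = overlap,
                     demean = FALSE)
  max(5 * sp$max_power, 1e-12)
}

#' Order-parameter phase diagram over (heterogeneity, coupling strength)
#'
#' For every grid cell a fresh network is built (sub-seeded per cell), run
#' autonomously, and its max-power order parameter compared against the
#' matched-silent threshold of its heterogeneity level; the analytic
#' critical coupling of each heterogeneity level is attached for overlay.
#'
#' @param het Numeric vector of heterogeneity-axis values (e.g. the GPA
#'   fraction `p`, or an adaptation spread `sigma_beta`).
#' @param g Numeric vector of coupling strengths.
#' @param spec_fn Function of one heterogeneity value returning
#'   `list(gamma_dist = , beta_dist = )`.
#' @param N Network size per cell.
#' @param seed Master seed; each cell uses an independent sub-stream.
#' @param T_run,T_trans,dt,nfft Simulation and estimator settings. Runs with
#'   `|g - gc|/gc < boundary_widen` use a doubled `T_run` and `T_trans`.
#' @param boundary_widen Relative distance to `gc` within which runs are
#'   lengthened (default `0.1`).
#' @return A tibble with columns `het`, `g`, `order_parameter`, `threshold`,
#'   `dynamic` (logical), `gc_analytic`, `seed`, `N`. Cells whose simulation
#'   fails are recorded with `NA` order parameter, not dropped.
#' @export
phase_diagram <- function(het, g, spec_fn, N = 500, seed = 1, T_run = 200,
                          T_trans = 50, dt = 0.02, nfft = 1024,
                          boundary_widen = 0.1) {
  cells <- tidyr::expand_grid(het = het, g = g)
  res <- purrr::pmap(cells, function(het, g) {
    spec <- spec_fn(het)
    gc <- tryCatch(
      critical_coupling(spec$gamma_dist, spec$beta_dist)$gc,
      error = function(e) NA_real_
    )
    cell_seed <- sub_seed(seed, sprintf("cell_%g_%g", het, g))
    near <- is.finite(gc) && abs(g - gc) / gc < boundary_widen
    Tr <- if (near) 2 * T_run else T_run
    Tt <- if (near) 2 * T_trans else T_trans
    model <- build_network(spec$gamma_dist, spec$beta_dist, N = N, g = g,
                           seed = cell_seed)
    ops <- tryCatch(
      op_two_windows(model, T_run = Tr, T_trans = Tt, dt = dt,
                     seed = cell_seed, nfft = nfft),
      error = function(e) list(op = NA_real_, first = NA_real_,
                               final = NA_real_)
    )
    thr <- silent_threshold(model, T_run = Tr, T_trans = Tt, dt = dt,
                            seed = cell_seed, nfft = nfft)
    # dynamic = above the numerical floor AND not still decaying across the
    # window (see op_two_windows)
    dyn <- is.finite(ops$final) && ops$final > thr &&
      ops$final > 0.2 * ops$first
    tibble::tibble(order_parameter = ops$op, op_first_half = ops$first,
                   op_final_half = ops$final, threshold = thr,
                   dynamic = dyn, gc_analytic = gc, seed = cell_seed, N = N)
  })
  out <- dplyr::bind_cols(cells, dplyr::bind_rows(res))
  class(out) <- c("phase_diagram", class(out))
  out
}

#' Empirical silent-to-dynamic boundary of a phase diagram
#'
#' For each heterogeneity value, the boundary is the geometric mean of the
#' largest silent `g` and the smallest dynamic `g` above it (NA when a side
#' is missing, i.e. the grid does not bracket the transition).
#'
#' @param pd A [phase_diagram()] tibble.
#' @return A tibble with columns `het`, `g_boundary`, `gc_analytic`.
#' @export
empirical_boundary <- function(pd) {
  dplyr::summarise(
    dplyr::group_by(pd, .data$het),
    g_boundary = {
      gs <- sort(.data$g)
      dyn <- .data$dynamic[order(.data$g)]
      k <- which(dyn)[1]
      if (is.na(k)) NA_real_
      else if (k == 1) NA_real_
      else sqrt(gs[k - 1] * gs[k])
    },
    gc_analytic = .data$gc_analytic[1],
    .groups = "drop"
  )
}
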