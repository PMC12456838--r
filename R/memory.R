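#' Reservoir-computing memory capacity of a driven network
#'
#' Drives the network with a single shared Gaussian white-noise signal
#' `u` (Euler-Maruyama, per-step variance `sigma_in^2 * dt`) through fixed
#' random input weights, then for each delay `k` fits a ridge-regularised
#' linear readout from the network state `x(t)` to the delayed input
#' `u(t - k)` on a chronological training segment and scores the squared
#' Pearson correlation on the held-out segment (the standard linear
#' memory function). The total capacity is the sum over delays.
#'
#' @param model A [network_model][build_network].
#' @param sigma_in Input amplitude scale.
#' @param input_weights_seed Seed for the i.i.d. standard-normal per-neuron
#'   input weights.
#' @param input_weights Optional explicit weight vector overriding the
#'   seeded draw.
#' @param dt Integration step.
#' @param T Post-transient drive duration (time units). Must give at least
#'   ~1000 training samples per delay.
#' @param T_trans Discarded transient.
#' @param delays Delay lags in time units (default multiples of 0.2 up to 20).
#' @param ridge Ridge penalty, applied as `ridge * trace(X'X)/N * I`.
#' @param split Fraction of samples used for training (chronological).
#' @param seed Seed of the noise path.
#' @param keep_data Also return the design matrix and input series (for
#'   cross-checking the readout externally).
#' @return A `memory_capacity`: tibble-backed fields `delays`,
#'   `mc_per_delay` (each in `[0, 1]`), `mc_total`, `flags` (delays with
#'   zero-variance predictions scored 0), and `settings`.
#' @export
run_memory_capacity <- function(model, sigma_in = 0.1, input_weights_seed = 1,
                                dt = 0.02, T = 400, T_trans = 50,
                                delays = seq(0.2, 20, by = 0.2),
                                ridge = 1e-6, split = 0.5, seed = 1,
                                keep_data = FALSE, input_weights = NULL) {
  stopifnot(inherits(model, "network_model"))
  N <- model$population$N
  w <- input_weights %||% with_rng(input_weights_seed, stats::rnorm(N))
  inp <- input_white_noise(sigma_in, w)
  x0 <- with_rng(sub_seed(seed, "init"), stats::rnorm(N))
  tr <- integrate_network(model, inp, x0 = x0, dt = dt,
                          T_total = T_trans + T, seed = sub_seed(seed, "input"),
                          record = "x")
  keep <- tr$times >= T_trans
  X <- tr$x[keep, , drop = FALSE]
  u <- tr$u[keep]

  ks <- as.integer(round(delays / dt))
  kmax <- max(ks)
  rows <- (kmax + 1L):nrow(X)
  if (length(rows) < 100) {
    rlang::abort("drive too short for the requested delays.",
                 class = "hetnetdyn_length_error")
  }
  n_train <- as.integer(floor(split * length(rows)))
  if (n_train < 1000) {
    rlang::warn(sprintf(
      "only %d training samples per delay; >= 1000 recommended.", n_train
    ))
  }
  tr_rows <- rows[seq_len(n_train)]
  te_rows <- rows[(n_train + 1L):length(rows)]
  sc <- mc_scores(X, u, ks, tr_rows, te_rows, ridge)

  structure(
    list(
      delays = delays, mc_per_delay = sc$score,
      mc_total = sum(sc$score), flags = sc$flagged,
      settings = list(sigma_in = sigma_in,
                      input_weights_seed = input_weights_seed, dt = dt,
                      T = T, T_trans = T_trans, ridge = ridge, split = split,
                      seed = seed, n_train = n_train, n_test = length(te_rows)),
      data = if (keep_data) {
        list(X = X, u = u, train_rows = tr_rows, test_rows = te_rows,
             lambda = sc$lambda)
      } else NULL
    ),
    class = "memory_capacity"
  )
}

# Ridge readout + squared-Pearson scoring for each delay (in steps).
# X: state matrix, u: input series aligned with X's rows; tr/te: row indices.
mc_scores <- function(X, u, ks, tr_rows, te_rows, ridge) {
  N <- ncol(X)
  Xtr <- X[tr_rows, , drop = FALSE]
  Xte <- X[te_rows, , drop = FALSE]
  mu <- colMeans(Xtr)
  Xtr <- sweep(Xtr, 2, mu)
  Xte <- sweep(Xte, 2, mu)
  XtX <- crossprod(Xtr)
  lam <- ridge * sum(diag(XtX)) / N
  R <- tryCatch(chol(XtX + diag(lam, N)), error = function(e) NULL)
  sc <- vapply(ks, function(k) {
    y_tr <- u[tr_rows - k]
    y_te <- u[te_rows - k]
    ybar <- mean(y_tr)
    if (is.null(R) || stats::var(y_te) == 0) return(c(0, 1))
    b <- backsolve(R, backsolve(R, crossprod(Xtr, y_tr - ybar),
                                transpose = TRUE))
    pred <- as.vector(Xte %*% b)
    if (stats::var(pred) == 0) return(c(0, 1))
    c(stats::cor(pred, y_te)^2, 0)
  }, numeric(2))
  list(score = sc[1, ], flagged = sc[2, ] > 0, lambda = lam)
}

#' @export
print.memory_capacity <- function(x, ...) {
  cat(sprintf("<memory_capacity: MC = %.3f over %d delays (max per-delay %.3f)>\n",
              x$mc_total, length(x$delays), max(x$mc_per_delay)))
  invisible(x)
}

#' Memory capacity versus coupling strength
#'
#' One [run_memory_capacity()] per grid point with matched seeds (fresh
#' network per `g`, same input-weight and noise streams), with the analytic
#' critical coupling attached. Near the transition the capacity is expected
#' to peak just below `gc`.
#'
#' @param g Numeric vector of coupling strengths.
#' @param gamma_dist,beta_dist Parameter distributions.
#' @param N Network size.
#' @param seed Master seed.
#' @param ... Passed to [run_memory_capacity()].
#' @return A tibble `g`, `mc_total`, `gc_analytic` (failed cells keep `NA`).
#' @export
capacity_curve <- function(g, gamma_dist, beta_dist, N = 300, seed = 1, ...) {
  gc <- critical_coupling(gamma_dist, beta_dist)$gc
  rows <- purrr::map(g, function(gi) {
    ms <- sub_seed(seed, sprintf("mc_g_%g", gi))
    mc <- tryCatch({
      model <- build_network(gamma_dist, beta_dist, N = N, g = gi, seed = ms)
      run_memory_capacity(model, input_weights_seed = sub_seed(seed, "win"),
                          seed = sub_seed(seed, "noise"), ...)$mc_total
    }, error = function(e) NA_real_)
    tibble::tibble(g = gi, mc_total = mc)
  })
  out <- dplyr::bind_rows(rows)
  out$gc_analytic <- gc
  out
}
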