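#' Jacobian of the network dynamics at the trivial fixed point
#'
#' Linearising the two-variable network around the origin (where the tanh
#' slope is 1) gives the `2N x 2N` block matrix
#' \deqn{\begin{pmatrix} J - I & I \\ \mathrm{diag}(\beta) & -\mathrm{diag}(\gamma) \end{pmatrix},}
#' whose spectral abscissa (maximum real part of the eigenvalues) decides
#' the linear stability of the quiescent state.
#'
#' @param model A [network_model][build_network].
#' @return A plain `2N x 2N` numeric matrix, states ordered `(x, a)`.
#' @export
jacobian_origin <- function(model) {
  N <- model$population$N
  J <- model$coupling$J # phi'(0) = 1 for both tanh and linear
  rbind(
    cbind(J - diag(N), diag(N)),
    cbind(diag(model$population$beta, N), diag(-model$population$gamma, N))
  )
}

#' Eigenspectrum of the Jacobian at the trivial fixed point
#'
#' Dense eigendecomposition of [jacobian_origin()]. The `2N` eigenvalues are
#' closed under complex conjugation (real matrix); the fixed point is
#' linearly stable iff the spectral abscissa is negative.
#'
#' @param model A [network_model][build_network].
#' @param guard_N Refuse dense decomposition beyond this network size.
#' @return An `eigen_spectrum`: `eigenvalues` (complex, length 2N),
#'   `spectral_abscissa`, and model provenance.
#' @export
eigenspectrum <- function(model, guard_N = 5000) {
  N <- model$population$N
  if (N > guard_N) {
    abort_param(sprintf(
      "N = %d exceeds the dense-eigendecomposition guard (%d); reduce N.",
      N, guard_N
    ))
  }
  ev <- eigen(jacobian_origin(model), only.values = TRUE)$values
  structure(
    list(eigenvalues = ev, spectral_abscissa = max(Re(ev)),
         model_ref = list(N = N, g = model$coupling$g,
                          seed = model$metadata$seed)),
    class = "eigen_spectrum"
  )
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("<eigen_spectrum: %d eigenvalues, spectral abscissa %.5g>\n",
              length(x$eigenvalues), x$spectral_abscissa))
  invisible(x)
}

#' @method as_tibble eigen_spectrum
#' @export
as_tibble.eigen_spectrum <- function(x, ...) {
  tibble::tibble(re = Re(x$eigenvalues), im = Im(x$eigenvalues))
}

#' Maximum Lyapunov exponent by the Benettin tangent-vector method
#'
#' Co-integrates the full nonlinear dynamics and its exact tangent dynamics
#' (the Jacobian along the trajectory applied to a tangent vector),
#' renormalising the tangent every `renorm_interval` time units and
#' averaging the accumulated log growth per unit time. Repeated over
#' `n_init` random initial conditions; a positive mean exponent diagnoses
#' chaos.
#'
#' @param model A [network_model][build_network].
#' @param dt Integration step.
#' @param T_trans Transient discarded before tangent accumulation.
#' @param T_measure Accumulation duration (must be many renorm intervals).
#' @param renorm_interval Time between tangent renormalisations.
#' @param n_init Number of random initial conditions.
#' @param seed Master seed; initial conditions and tangents are sub-seeded.
#' @return A `lyapunov_estimate`: `lambda` (per-realisation exponents),
#'   `lambda_max` (their mean), `std`, and `settings`.
#' @export
max_lyapunov_benettin <- function(model, dt = 0.02, T_trans = 50,
                                  T_measure = 200, renorm_interval = 1,
                                  n_init = 10, seed = 1) {
  stopifnot(inherits(model, "network_model"))
  if (T_measure < 10 * renorm_interval) {
    abort_param("`T_measure` must cover many renormalisation intervals.")
  }
  pop <- model$population
  N <- pop$N
  J <- model$coupling$J
  gamma <- pop$gamma
  beta <- pop$beta
  act <- activation_fn(pop$activation)
  steps_trans <- as.integer(round(T_trans / dt))
  steps_meas <- as.integer(round(T_measure / dt))
  renorm_every <- max(1L, as.integer(round(renorm_interval / dt)))

  lambdas <- vapply(seq_len(n_init), function(r) {
    rs <- sub_seed(seed, sprintf("lyap_init_%d", r))
    init <- with_rng(rs, list(x = stats::rnorm(N), v = stats::rnorm(2 * N)))
    x <- init$x
    a <- numeric(N)
    v <- init$v / sqrt(sum(init$v^2))
    vx <- v[1:N]
    va <- v[(N + 1):(2 * N)]
    # transient: co-evolve the tangent (renormalised, growth discarded) so
    # it is aligned with the leading direction when accumulation starts
    for (n in seq_len(steps_trans)) {
      s <- act$phi(x)
      d <- act$dphi(x)
      xn <- x + dt * (-x + a + as.vector(J %*% s))
      an <- a + dt * (-gamma * a + beta * x)
      vxn <- vx + dt * (-vx + va + as.vector(J %*% (d * vx)))
      van <- va + dt * (beta * vx - gamma * va)
      x <- xn; a <- an; vx <- vxn; va <- van
      if (n %% renorm_every == 0L) {
        nrm <- sqrt(sum(vx^2) + sum(va^2))
        vx <- vx / nrm
        va <- va / nrm
      }
    }
    nrm <- sqrt(sum(vx^2) + sum(va^2))
    vx <- vx / nrm
    va <- va / nrm
    log_acc <- 0
    for (n in seq_len(steps_meas)) {
      s <- act$phi(x)
      d <- act$dphi(x)
      xn <- x + dt * (-x + a + as.vector(J %*% s))
      an <- a + dt * (-gamma * a + beta * x)
      vxn <- vx + dt * (-vx + va + as.vector(J %*% (d * vx)))
      van <- va + dt * (beta * vx - gamma * va)
      x <- xn; a <- an; vx <- vxn; va <- van
      if (n %% renorm_every == 0L || n == steps_meas) {
        nrm <- sqrt(sum(vx^2) + sum(va^2))
        if (nrm == 0 || !is.finite(nrm)) {
          rlang::abort("tangent vector norm vanished or diverged.",
                       class = "hetnetdyn_numeric_error")
        }
        log_acc <- log_acc + log(nrm)
        vx <- vx / nrm
        va <- va / nrm
      }
      if (n %% 250L == 0L) {
        m <- max(abs(x))
        if (!is.finite(m) || m > 1e6) {
          rlang::abort("trajectory diverged during Lyapunov estimation.",
                       class = "hetnetdyn_divergence_error", step = n)
        }
      }
    }
    log_acc / (steps_meas * dt)
  }, numeric(1))

  structure(
    list(
      lambda = lambdas, lambda_max = mean(lambdas),
      std = if (n_init > 1) stats::sd(lambdas) else 0,
      settings = list(dt = dt, T_trans = T_trans, T_measure = T_measure,
                      renorm_interval = renorm_interval, n_init = n_init,
                      seed = seed)
    ),
    class = "lyapunov_estimate"
  )
}

#' @export
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf("<lyapunov_estimate: lambda_max = %.5g +/- %.3g (%d inits)>\n",
              x$lambda_max, x$std, length(x$lambda)))
  invisible(x)
}

#' Lyapunov exponent versus coupling strength
#'
#' Builds one fresh network per `g` (sub-seeded) from the given parameter
#' distributions and estimates its maximum Lyapunov exponent. The analytic
#' critical coupling is attached for comparison.
#'
#' @param g Numeric vector of coupling strengths.
#' @param gamma_dist,beta_dist Parameter distributions.
#' @param N Network size.
#' @param seed Master seed.
#' @param ... Passed to [max_lyapunov_benettin()].
#' @return A tibble `g`, `lambda_max`, `std`, `n_init`, `gc_analytic`.
#' @export
lyapunov_curve <- function(g, gamma_dist, beta_dist, N = 500, seed = 1, ...) {
  gc <- critical_coupling(gamma_dist, beta_dist)$gc
  rows <- purrr::map(g, function(gi) {
    ms <- sub_seed(seed, sprintf("lyap_g_%g", gi))
    model <- build_network(gamma_dist, beta_dist, N = N, g = gi, seed = ms)
    est <- max_lyapunov_benettin(model, seed = ms, ...)
    tibble::tibble(g = gi, lambda_max = est$lambda_max, std = est$std,
                   n_init = length(est$lambda))
  })
  out <- dplyr::bind_rows(rows)
  out$gc_analytic <- gc
  out
}

#' Zero crossing of a Lyapunov curve
#'
#' Linear interpolation between the bracketing grid points of the mean
#' exponent curve; `NA` when the curve does not change sign.
#'
#' @param curve A tibble from [lyapunov_curve()] (columns `g`, `lambda_max`).
#' @return The interpolated `g` at which the mean exponent crosses zero.
#' @export
lyapunov_crossing <- function(curve) {
  curve <- curve[order(curve$g), ]
  lam <- curve$lambda_max
  k <- which(lam[-length(lam)] < 0 & lam[-1] >= 0)[1]
  if (is.na(k)) return(NA_real_)
  g1 <- curve$g[k]; g2 <- curve$g[k + 1]
  l1 <- lam[k]; l2 <- lam[k + 1]
  g1 - l1 * (g2 - g1) / (l2 - l1)
}
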