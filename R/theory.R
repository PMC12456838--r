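#' Transfer gain of the two-variable neuron
#'
#' Squared-magnitude frequency response relating the power spectral density
#' of a neuron's activity to that of its (mean-field) input:
#' \deqn{G(\omega;\gamma,\beta) = \frac{\omega^2+\gamma^2}
#'   {\omega^4+(\gamma^2+2\beta+1)\omega^2+(\gamma-\beta)^2}.}
#' At `omega = 0` this is `gamma^2/(gamma-beta)^2`; with `beta = 0` it
#' reduces to the one-variable leaky-integrator gain `1/(omega^2+1)`. For
#' `gamma > beta > 0` the gain is maximal at `omega = 0`; for `beta < 0`
#' (adaptation) the maximum can sit at a nonzero frequency.
#'
#' @param omega Angular frequency (rad per time unit); vectorised.
#' @param gamma Decay rate of the auxiliary variable.
#' @param beta Feedback strength.
#' @return Non-negative gain values, even in `omega`.
#' @export
#' @examples
#' transfer_gain(0, gamma = 10, beta = 0.5) # 100/90.25
transfer_gain <- function(omega, gamma, beta) {
  if (any(gamma == beta) && any(omega == 0)) {
    rlang::abort("transfer gain is singular at omega = 0 when gamma == beta.",
                 class = "hetnetdyn_singular_error")
  }
  o2 <- omega^2
  (o2 + gamma^2) / (o2^2 + (gamma^2 + 2 * beta + 1) * o2 + (gamma - beta)^2)
}

#' Population-averaged transfer gain
#'
#' Expectation of [transfer_gain()] over the joint (product) distribution of
#' the intrinsic parameters, `Gbar(omega) = E[G(omega; gamma, beta)]`. For
#' discrete specifications this is a finite mixture (exact); continuous
#' specifications use fixed-order Gauss-Legendre quadrature per dimension
#' (tensor product when both are continuous).
#'
#' The averaged gain is what determines the order-chaos transition: the
#' quiescent state is stable when `g^2 * max_omega Gbar(omega) < 1`.
#'
#' @param omega Angular frequency; vectorised.
#' @param gamma_dist,beta_dist [param_dist][dist_constant] objects (a bare
#'   number is promoted to a constant distribution).
#' @param nodes Gauss-Legendre node count per continuous dimension.
#' @return `Gbar(omega)`, same length as `omega`.
#' @export
averaged_gain <- function(omega, gamma_dist, beta_dist, nodes = 64) {
  gamma_dist <- as_param_dist(gamma_dist)
  beta_dist <- as_param_dist(beta_dist)
  check_gain_support(gamma_dist, beta_dist)
  ng <- dist_nodes(gamma_dist, nodes)
  nb <- dist_nodes(beta_dist, nodes)
  ga <- rep(ng$x, times = length(nb$x))
  be <- rep(nb$x, each = length(ng$x))
  w <- rep(ng$w, times = length(nb$x)) * rep(nb$w, each = length(ng$x))
  vapply(omega, function(om) sum(w * transfer_gain(om, ga, be)), numeric(1))
}

as_param_dist <- function(x) {
  if (inherits(x, "param_dist")) x else dist_constant(x)
}

check_gain_support <- function(gamma_dist, beta_dist) {
  if (min(dist_support(gamma_dist)) <= max(dist_support(beta_dist))) {
    rlang::abort(
      "parameter support includes gamma <= beta: the averaged gain diverges.",
      class = "hetnetdyn_singular_error"
    )
  }
  invisible(NULL)
}

# Maximize f over omega >= 0: candidates {0} + log-spaced grid, then
# golden-section refinement around the best candidate; ties broken toward
# smaller omega.
maximize_over_omega <- function(f, grid_lo = 1e-3, grid_hi = 1e3,
                                grid_n = 200, refine = TRUE) {
  om <- c(0, 10^seq(log10(grid_lo), log10(grid_hi), length.out = grid_n))
  vals <- f(om)
  k <- which.max(vals) # which.max returns the first (smallest-omega) maximum
  om_star <- om[k]
  f_star <- vals[k]
  if (refine && k > 1) {
    lo <- om[max(1, k - 1)]
    hi <- om[min(length(om), k + 1)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    if (opt$objective > f_star) {
      om_star <- opt$maximum
      f_star <- opt$objective
    }
  }
  list(omega = om_star, value = f_star)
}

new_critical_coupling <- function(gc, omega_star, gain_max, method, spec) {
  structure(
    list(gc = gc, omega_star = omega_star, gain_max = gain_max,
         method = method, spec = spec),
    class = "critical_coupling"
  )
}

#' @export
print.critical_coupling <- function(x, ...) {
  cat(sprintf("<critical_coupling: gc = %.6g at omega* = %.4g (%s)>\n",
              x$gc, x$omega_star, x$method))
  invisible(x)
}

#' Critical coupling strength from the averaged-gain condition
#'
#' Solves `max_omega Gbar(omega) * gc^2 = 1` for the critical coupling
#' `gc = 1 / sqrt(max_omega Gbar(omega))`, the point at which the quiescent
#' fixed point of the heterogeneous network loses stability and sustained
#' chaotic activity becomes possible. When every neuron satisfies
#' `gamma > beta >= 0` the maximum sits at `omega = 0`; with adaptation
#' (`beta < 0`) it can move to a nonzero frequency, so the maximization is
#' always performed over a `{0} + log-spaced` frequency grid with local
#' refinement.
#'
#' @inheritParams averaged_gain
#' @return A `critical_coupling` object: fields `gc`, `omega_star`,
#'   `gain_max`, `method` and the distribution `spec`. See [tidy()] methods.
#' @export
#' @examples
#' # uniform feedback heterogeneity, gamma = 3: gc = 1/sqrt(30) = 0.1826
#' critical_coupling(dist_constant(3), dist_uniform(0, 2.9))
critical_coupling <- function(gamma_dist, beta_dist, nodes = 64) {
  gamma_dist <- as_param_dist(gamma_dist)
  beta_dist <- as_param_dist(beta_dist)
  check_gain_support(gamma_dist, beta_dist)
  best <- maximize_over_omega(function(om) {
    averaged_gain(om, gamma_dist, beta_dist, nodes = nodes)
  })
  new_critical_coupling(
    gc = 1 / sqrt(best$value), omega_star = best$omega, gain_max = best$value,
    method = "quadrature_general",
    spec = list(gamma_dist = dist_to_list(gamma_dist),
                beta_dist = dist_to_list(beta_dist))
  )
}

#' Closed-form critical coupling for a two-point decay-rate distribution
#'
#' With `gamma` drawn from `{gamma_low (prob p), gamma_high (prob 1-p)}` and
#' constant `beta`, subject to `gamma_high > gamma_low > beta >= 0`, the
#' averaged gain is maximal at `omega = 0` and
#' \deqn{g_c = \left(p\frac{\gamma_{low}^2}{(\gamma_{low}-\beta)^2}
#'   + (1-p)\frac{\gamma_{high}^2}{(\gamma_{high}-\beta)^2}\right)^{-1/2}.}
#' At `p = 0` this simplifies to `1 - beta/gamma_high`, recovering the
#' conventional `gc = 1` as `gamma_high -> Inf` or `beta -> 0`; it is
#' strictly decreasing in `p`, so adding slow (GPA) neurons always enlarges
#' the dynamic regime.
#'
#' @param p Probability of the low decay rate (the GPA fraction).
#' @param gamma_low,gamma_high The two decay rates.
#' @param beta Constant feedback strength, `0 <= beta < gamma_low`.
#' @return A `critical_coupling` object with `omega_star = 0`.
#' @export
critical_coupling_two_point <- function(p, gamma_low, gamma_high, beta) {
  if (!(gamma_high > gamma_low)) abort_param("need gamma_high > gamma_low.")
  if (!(gamma_low > beta) || beta < 0) {
    abort_param("need gamma_low > beta >= 0.")
  }
  if (p < 0 || p > 1) abort_param("`p` must be in [0, 1].")
  gain0 <- p * (gamma_low / (gamma_low - beta))^2 +
    (1 - p) * (gamma_high / (gamma_high - beta))^2
  new_critical_coupling(
    gc = 1 / sqrt(gain0), omega_star = 0, gain_max = gain0,
    method = "closed_form_two_point",
    spec = list(p = p, gamma_low = gamma_low, gamma_high = gamma_high,
                beta = beta)
  )
}

#' Naive Gaussian-mean-field prediction for adaptation heterogeneity
#'
#' The earlier approximation that treats Gaussian heterogeneity of the
#' feedback strength `beta ~ N(mu_beta, sigma_beta^2)` (adaptation,
#' `mu_beta < 0`) as an extra Gaussian mean field. Its effective gain is
#' \deqn{G_\beta(\omega) = \frac{G(\omega;\gamma,\mu_\beta)}
#'   {1 - \frac{\sigma_\beta^2}{\gamma^2+\omega^2}G(\omega;\gamma,\mu_\beta)},}
#' and the predicted transition is `ghat_c = 1/sqrt(max_omega G_beta)`.
#' This prediction *decreases* with `sigma_beta`, whereas the correct
#' averaged-gain prediction ([critical_coupling()] with a truncated-normal
#' `beta`) increases — the two theories can disagree even in direction.
#'
#' @param gamma Constant decay rate.
#' @param mu_beta Mean feedback strength (typically negative).
#' @param sigma_beta Heterogeneity scale, `>= 0`.
#' @return A `critical_coupling` object with `method = "naive_gaussian"`.
#'   If the denominator of the effective gain is non-positive anywhere on
#'   the frequency scan the naive theory has broken down and an error of
#'   class `hetnetdyn_naive_breakdown_error` is raised.
#' @export
naive_critical_coupling <- function(gamma, mu_beta, sigma_beta) {
  if (sigma_beta < 0) abort_param("`sigma_beta` must be >= 0.")
  if (gamma <= mu_beta) abort_param("need gamma > mu_beta.")
  gb <- function(om) {
    g0 <- transfer_gain(om, gamma, mu_beta)
    den <- 1 - sigma_beta^2 / (gamma^2 + om^2) * g0
    if (any(den <= 0)) {
      rlang::abort(
        "naive Gaussian-mean-field gain has a non-positive denominator; the approximation breaks down for this sigma_beta.",
        class = "hetnetdyn_naive_breakdown_error"
      )
    }
    g0 / den
  }
  best <- maximize_over_omega(gb)
  new_critical_coupling(
    gc = 1 / sqrt(best$value), omega_star = best$omega, gain_max = best$value,
    method = "naive_gaussian",
    spec = list(gamma = gamma, mu_beta = mu_beta, sigma_beta = sigma_beta)
  )
}
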