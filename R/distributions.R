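#' Intrinsic-parameter distributions
#'
#' Constructors for the distributions from which per-neuron intrinsic
#' parameters (the auxiliary-variable decay rate `gamma` and the feedback
#' strength `beta`) are drawn. Four families are supported:
#'
#' * `dist_constant(value)` — every neuron shares the same value.
#' * `dist_two_point(p, low, high)` — `low` with probability `p`, `high`
#'   with probability `1 - p`. With a small decay rate modelling
#'   graded-persistent-activity (GPA) neurons and a large one modelling
#'   normal neurons, `p` is the GPA fraction of the network.
#' * `dist_uniform(lo, hi)` — continuous uniform on `[lo, hi]`.
#' * `dist_truncnorm(mu, sigma, lo, hi)` — normal `N(mu, sigma^2)` truncated
#'   to `[lo, hi]`, used for Gaussian heterogeneity of the adaptation
#'   feedback strength (negative `beta`).
#'
#' @param value,p,low,high,lo,hi,mu,sigma Numeric distribution parameters.
#' @return An object of class `param_dist`.
#' @seealso [sample_params()], [dist_expect()], [dist_mean()]
#' @export
#' @examples
#' d <- dist_two_point(p = 0.5, low = 1, high = 10)
#' sample_params(d, 5, seed = 1)
#' dist_mean(d)
dist_constant <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  new_param_dist("constant", list(value = value))
}

#' @rdname dist_constant
#' @export
dist_two_point <- function(p, low, high) {
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
    abort_param("`p` must be a probability in [0, 1].")
  }
  if (!(low < high)) abort_param("two-point distribution requires low < high.")
  new_param_dist("two_point", list(p = p, low = low, high = high))
}

#' @rdname dist_constant
#' @export
dist_uniform <- function(lo, hi) {
  if (!(lo < hi)) abort_param("uniform distribution requires lo < hi.")
  new_param_dist("uniform", list(lo = lo, hi = hi))
}

#' @rdname dist_constant
#' @export
dist_truncnorm <- function(mu, sigma, lo = mu - 5 * sigma, hi = mu + 5 * sigma) {
  if (!is.numeric(sigma) || sigma < 0) abort_param("`sigma` must be >= 0.")
  if (!(lo < hi)) abort_param("truncated normal requires lo < hi.")
  new_param_dist("truncated_normal", list(mu = mu, sigma = sigma, lo = lo, hi = hi))
}

new_param_dist <- function(kind, params) {
  structure(list(kind = kind, params = params), class = "param_dist")
}

#' @export
print.param_dist <- function(x, ...) {
  pars <- paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  cat(sprintf("<param_dist: %s(%s)>\n", x$kind, pars))
  invisible(x)
}

#' Draw i.i.d. samples from an intrinsic-parameter distribution
#'
#' @param dist A [param_dist][dist_constant] object.
#' @param n Number of draws.
#' @param seed Optional integer seed; the draw is a pure function of
#'   `(dist, n, seed)` and does not disturb the global RNG stream.
#' @return Numeric vector of length `n`. Truncated-normal draws use the
#'   inverse-CDF on the truncated range, so they always lie in `[lo, hi]`.
#' @export
sample_params <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "param_dist"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort_param("`n` must be >= 1.")
  n <- as.integer(n)
  p <- dist$params
  with_rng(seed, switch(dist$kind,
    constant = rep(p$value, n),
    two_point = ifelse(stats::runif(n) < p$p, p$low, p$high),
    uniform = stats::runif(n, p$lo, p$hi),
    truncated_normal = {
      if (p$sigma == 0) {
        rep(min(max(p$mu, p$lo), p$hi), n)
      } else {
        plo <- stats::pnorm(p$lo, p$mu, p$sigma)
        phi <- stats::pnorm(p$hi, p$mu, p$sigma)
        stats::qnorm(plo + stats::runif(n) * (phi - plo), p$mu, p$sigma)
      }
    }
  ))
}

#' Support, mean and expectations of a parameter distribution
#'
#' `dist_support()` returns the closed support `[min, max]`. `dist_mean()`
#' is the exact mean. `dist_expect()` computes `E[f(X)]`: exactly for the
#' discrete families (finite mixtures) and by fixed-order Gauss–Legendre
#' quadrature for the continuous ones.
#'
#' @param dist A [param_dist][dist_constant] object.
#' @param f A vectorised function of one numeric argument.
#' @param nodes Gauss–Legendre node count for continuous families.
#' @return `dist_support()`: length-2 numeric; `dist_mean()`,
#'   `dist_expect()`: a single numeric value.
#' @export
dist_support <- function(dist) {
  p <- dist$params
  switch(dist$kind,
    constant = c(p$value, p$value),
    two_point = c(p$low, p$high),
    uniform = c(p$lo, p$hi),
    truncated_normal = c(p$lo, p$hi)
  )
}

#' @rdname dist_support
#' @export
dist_mean <- function(dist) {
  dist_expect(dist, identity)
}

#' @rdname dist_support
#' @export
dist_expect <- function(dist, f, nodes = 64) {
  nd <- dist_nodes(dist, nodes)
  sum(nd$w * f(nd$x))
}

# Quadrature/atom representation: points x and weights w with sum(w) == 1.
# Exact for the discrete families; for continuous families the weights fold
# in the density (self-normalised, so truncated-normal mass is consistent
# with the same node set).
dist_nodes <- function(dist, nodes = 64) {
  p <- dist$params
  switch(dist$kind,
    constant = list(x = p$value, w = 1),
    two_point = list(x = c(p$low, p$high), w = c(p$p, 1 - p$p)),
    uniform = {
      gl <- pracma::gaussLegendre(nodes, p$lo, p$hi)
      list(x = gl$x, w = gl$w / (p$hi - p$lo))
    },
    truncated_normal = {
      if (p$sigma == 0) {
        list(x = min(max(p$mu, p$lo), p$hi), w = 1)
      } else {
        gl <- pracma::gaussLegendre(nodes, p$lo, p$hi)
        w <- gl$w * stats::dnorm(gl$x, p$mu, p$sigma)
        list(x = gl$x, w = w / sum(w))
      }
    }
  )
}

#' Serialise a parameter distribution to / from a plain list
#'
#' The list form is JSON-compatible and round-trips losslessly; it is what
#' run configurations and trajectory-container headers store.
#'
#' @param dist A [param_dist][dist_constant] object.
#' @param x A list with elements `kind` and the family's parameters.
#' @return `dist_to_list()`: a named list; `dist_from_list()`: a `param_dist`.
#' @export
dist_to_list <- function(dist) {
  c(list(kind = dist$kind), dist$params)
}

#' @rdname dist_to_list
#' @export
dist_from_list <- function(x) {
  kind <- x$kind
  x$kind <- NULL
  switch(kind,
    constant = dist_constant(x$value),
    two_point = dist_two_point(x$p, x$low, x$high),
    uniform = dist_uniform(x$lo, x$hi),
    truncated_normal = dist_truncnorm(x$mu, x$sigma, x$lo, x$hi),
    abort_param(sprintf("unknown distribution kind '%s'", kind))
  )
}
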