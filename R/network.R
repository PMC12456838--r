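#' Construct a heterogeneous neuron population
#'
#' A population is the collection of per-neuron intrinsic parameters of the
#' two-variable rate model
#' \deqn{\dot x_i = -x_i + a_i + I_i(t), \qquad \dot a_i = -\gamma_i a_i + \beta_i x_i,}
#' where `a` is a slow auxiliary variable fed back into the activity with
#' strength `beta` and decaying at rate `gamma`. Large `gamma` gives a
#' normal, promptly decaying neuron; `gamma` slightly above `beta > 0` gives
#' graded persistent activity; `beta < 0` gives adaptation.
#'
#' @param gamma Numeric vector of decay rates (all > 0), one per neuron.
#' @param beta Numeric vector (recycled if length 1) of feedback strengths.
#' @param activation `"tanh"` (default) or `"linear"`.
#' @param allow_unstable If `FALSE` (default), an error is raised when any
#'   neuron violates the single-neuron non-divergence condition
#'   `gamma_i > beta_i`. Set `TRUE` only for deliberate experimentation.
#' @return A `neuron_population` with fields `N`, `gamma`, `beta`,
#'   `activation` and the flag `stable_intrinsic` (`all(gamma > beta)`).
#' @export
neuron_population <- function(gamma, beta, activation = c("tanh", "linear"),
                              allow_unstable = FALSE) {
  activation <- match.arg(activation)
  if (length(beta) == 1) beta <- rep(beta, length(gamma))
  if (length(gamma) < 1) abort_param("population needs at least one neuron.")
  if (length(beta) != length(gamma)) {
    abort_param("`gamma` and `beta` must have the same length.")
  }
  if (any(gamma <= 0)) abort_param("all decay rates `gamma` must be > 0.")
  stable <- all(gamma > beta)
  if (!stable && !allow_unstable) {
    abort_param(paste0(
      "some neurons have gamma <= beta; their activity diverges without ",
      "coupling. Use allow_unstable = TRUE to override."
    ))
  }
  structure(
    list(N = length(gamma), gamma = as.numeric(gamma), beta = as.numeric(beta),
         activation = activation, stable_intrinsic = stable),
    class = "neuron_population"
  )
}

#' @export
print.neuron_population <- function(x, ...) {
  cat(sprintf(
    "<neuron_population: N = %d, activation = %s, stable_intrinsic = %s>\n",
    x$N, x$activation, x$stable_intrinsic
  ))
  invisible(x)
}

#' Sample a random Gaussian coupling matrix
#'
#' Off-diagonal entries are i.i.d. `N(0, g^2/N)`; diagonal entries are
#' exactly zero (no self-connections). `g` sets the overall coupling
#' strength and is the control parameter of the order-chaos transition.
#'
#' @param N Matrix dimension (neuron count).
#' @param g Coupling strength, `g >= 0`.
#' @param seed Optional integer seed; the draw is reproducible given it.
#' @return A `coupling_matrix` with fields `N`, `g`, `J` (N x N), `seed`.
#' @export
sample_coupling <- function(N, g, seed = NULL) {
  if (!is.numeric(N) || N < 1) abort_param("`N` must be >= 1.")
  if (!is.numeric(g) || g < 0) abort_param("`g` must be >= 0.")
  N <- as.integer(N)
  J <- with_rng(seed, matrix(stats::rnorm(N * N, sd = g / sqrt(N)), N, N))
  diag(J) <- 0
  structure(list(N = N, g = g, J = J, seed = seed), class = "coupling_matrix")
}

#' Build a heterogeneous random network model
#'
#' Samples the per-neuron decay rates and feedback strengths from the given
#' distributions and draws the Gaussian coupling matrix, using independent
#' named sub-streams of the master seed (`"gamma"`, `"beta"`, `"coupling"`),
#' so that e.g. enlarging the gamma draw does not change the coupling draw.
#'
#' @param gamma_dist,beta_dist [param_dist][dist_constant] objects for the
#'   decay rates and feedback strengths.
#' @param N Neuron count.
#' @param g Coupling strength.
#' @param seed Integer master seed (required: models are always rebuildable).
#' @param activation,allow_unstable Passed to [neuron_population()].
#' @return A `network_model` with fields `population`, `coupling`, and
#'   `metadata` recording seeds and distribution specs.
#' @export
#' @examples
#' net <- build_network(dist_two_point(0.5, 1, 10), dist_constant(0.5),
#'                      N = 100, g = 0.6, seed = 1)
#' net
build_network <- function(gamma_dist, beta_dist, N, g, seed,
                          activation = c("tanh", "linear"),
                          allow_unstable = FALSE) {
  stopifnot(inherits(gamma_dist, "param_dist"), inherits(beta_dist, "param_dist"))
  activation <- match.arg(activation)
  gamma <- sample_params(gamma_dist, N, seed = sub_seed(seed, "gamma"))
  beta <- sample_params(beta_dist, N, seed = sub_seed(seed, "beta"))
  pop <- neuron_population(gamma, beta, activation, allow_unstable)
  coup <- sample_coupling(N, g, seed = sub_seed(seed, "coupling"))
  structure(
    list(
      population = pop, coupling = coup,
      metadata = list(
        seed = seed,
        sub_seeds = list(gamma = sub_seed(seed, "gamma"),
                         beta = sub_seed(seed, "beta"),
                         coupling = sub_seed(seed, "coupling")),
        gamma_dist = dist_to_list(gamma_dist),
        beta_dist = dist_to_list(beta_dist)
      )
    ),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf(
    "<network_model: N = %d, g = %.4g, activation = %s, seed = %s>\n",
    x$population$N, x$coupling$g, x$population$activation,
    format(x$metadata$seed)
  ))
  invisible(x)
}

# Activation function and its derivative.
activation_fn <- function(activation) {
  switch(activation,
    tanh = list(phi = tanh, dphi = function(x) 1 - tanh(x)^2),
    linear = list(phi = identity, dphi = function(x) rep(1, length(x)))
  )
}
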