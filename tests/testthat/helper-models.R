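# Shared small fixtures, built in code.

two_point_spec <- function(p, low = 1, high = 10, beta = 0.5) {
  list(gamma_dist = dist_two_point(p, low, high), beta_dist = dist_constant(beta))
}

small_net <- function(N = 20, g = 0.5, p = 0.5, seed = 1, ...) {
  s <- two_point_spec(p)
  build_network(s$gamma_dist, s$beta_dist, N = N, g = g, seed = seed, ...)
}

# Closed-form state of one uncoupled linear neuron at time t:
# z' = A z + b (b constant), z(t) = e^{At}(z0 + A^{-1} b) - A^{-1} b.
linear_neuron_state <- function(gamma, beta, z0, t, b = c(0, 0)) {
  A <- matrix(c(-1, beta, 1, -gamma), 2, 2)
  eA <- as.matrix(Matrix::expm(A * t))
  if (all(b == 0)) return(as.vector(eA %*% z0))
  Ainvb <- solve(A, b)
  as.vector(eA %*% (z0 + Ainvb) - Ainvb)
}

# Slow/fast eigenvalues of the 2x2 single-neuron block.
neuron_eigen <- function(gamma, beta) {
  tr <- -(1 + gamma)
  det <- gamma - beta
  disc <- sqrt(tr^2 - 4 * det + 0i)
  sort(Re(c((tr + disc) / 2, (tr - disc) / 2)), decreasing = TRUE)
}
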