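test_that("single-neuron Jacobian eigenvalues match the quadratic formula", {
  m <- build_network(dist_constant(0.51), dist_constant(0.5), N = 1, g = 0,
                     seed = 1)
  ev <- sort(Re(eigenspectrum(m)$eigenvalues))
  # roots of lambda^2 + 1.51 lambda + 0.01
  roots <- sort(Re(polyroot(c(0.01, 1.51, 1))))
  expect_equal(ev, roots, tolerance = 1e-10)
  expect_equal(ev[2], -0.006655, tolerance = 1e-3)
})

test_that("Jacobian matches central finite differences of the vector field", {
  m <- small_net(N = 4, g = 0.7, seed = 2)
  Jac <- jacobian_origin(m)
  # vector field via a single tiny Euler step of the integrator
  f <- function(z) {
    tr <- integrate_network(m, x0 = z[1:4], a0 = z[5:8], dt = 1e-7,
                            T_total = 1e-7)
    (c(tr$x[1, ], tr$a[1, ]) - z) / 1e-7
  }
  h <- 1e-5
  num <- sapply(1:8, function(j) {
    e <- numeric(8); e[j] <- h
    (f(e) - f(-e)) / (2 * h)
  })
  expect_equal(max(abs(num - Jac)), 0, tolerance = 1e-6)
})

test_that("uncoupled homogeneous network: two eigenvalue locations, multiplicity N", {
  m <- build_network(dist_constant(5), dist_constant(0.5), N = 8, g = 0, seed = 1)
  es <- eigenspectrum(m)
  locs <- unique(round(es$eigenvalues, 10))
  expect_equal(length(locs), 2L)
  expect_equal(length(es$eigenvalues), 16L)
})

test_that("spectrum is conjugate-symmetric and the size guard triggers", {
  m <- small_net(N = 30, g = 1, seed = 3)
  es <- eigenspectrum(m)
  ev <- es$eigenvalues[order(Re(es$eigenvalues), Im(es$eigenvalues))]
  cj <- Conj(ev)[order(Re(Conj(ev)), Im(Conj(ev)))]
  expect_equal(ev, cj, tolerance = 1e-8)
  big <- m; big$population$N <- 6000
  expect_error(eigenspectrum(big), class = "hetnetdyn_parameter_error")
})

test_that("origin stability flips across the analytic transition point", {
  gc <- critical_coupling_two_point(0.5, 1, 5, 0.5)$gc
  sa <- sapply(1:5, function(s) {
    c(eigenspectrum(small_net(N = 300, g = 0.8 * gc, p = 0.5, seed = s))$spectral_abscissa,
      eigenspectrum(build_network(dist_two_point(0.5, 1, 5), dist_constant(0.5),
                                  N = 300, g = 1.3 * gc, seed = s))$spectral_abscissa)
  })
  expect_true(all(sa[1, ] < 0))
  expect_true(all(sa[2, ] > 0))
})

test_that("Benettin exponent of a linear network equals its spectral abscissa", {
  # slow GPA block: lambda ~ -0.0066515
  m <- build_network(dist_constant(0.51), dist_constant(0.5), N = 4, g = 0,
                     seed = 1)
  est <- max_lyapunov_benettin(m, T_trans = 20, T_measure = 200, n_init = 2,
                               seed = 1)
  expect_equal(est$lambda_max, neuron_eigen(0.51, 0.5)[1], tolerance = 1e-3)
  # heterogeneous uncoupled bank: abscissa of the block-diagonal Jacobian
  m2 <- small_net(N = 10, g = 0, seed = 4)
  est2 <- max_lyapunov_benettin(m2, T_trans = 20, T_measure = 150, n_init = 1,
                                seed = 2)
  expect_equal(est2$lambda_max, eigenspectrum(m2)$spectral_abscissa,
               tolerance = 1e-2)
})

test_that("estimate is insensitive to the renormalisation interval", {
  m <- small_net(N = 150, g = 2.5, seed = 9) # strongly chaotic
  l1 <- max_lyapunov_benettin(m, T_trans = 40, T_measure = 150,
                              renorm_interval = 1, n_init = 1, seed = 3)
  l2 <- max_lyapunov_benettin(m, T_trans = 40, T_measure = 150,
                              renorm_interval = 2, n_init = 1, seed = 3)
  expect_gt(l1$lambda_max, 0)
  expect_lt(abs(l1$lambda_max - l2$lambda_max),
            pmax(0.05 * abs(l1$lambda_max), 0.003))
})

test_that("lyapunov curve machinery: crossing interpolation", {
  curve <- tibble::tibble(g = c(0.5, 0.7, 0.9), lambda_max = c(-0.1, -0.02, 0.02))
  expect_equal(lyapunov_crossing(curve), 0.8)
  expect_true(is.na(lyapunov_crossing(tibble::tibble(g = 1:2,
                                                     lambda_max = c(-1, -2)))))
})
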