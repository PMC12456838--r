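test_that("transfer gain matches its closed-form special cases", {
  expect_equal(transfer_gain(0, 10, 0.5), 100 / 90.25, tolerance = 1e-12)
  expect_equal(transfer_gain(0, 3, 2), 9, tolerance = 1e-12)
  # beta = 0: one-variable leaky-integrator limit 1/(omega^2 + 1)
  om <- seq(0, 20, by = 0.5)
  expect_equal(transfer_gain(om, 4, 0), 1 / (om^2 + 1), tolerance = 1e-12)
  # even in omega
  expect_equal(transfer_gain(om, 2, 0.5), transfer_gain(-om, 2, 0.5))
  # gamma > beta > 0: maximum at omega = 0 on a dense grid
  grid <- c(0, 10^seq(-4, 3, length.out = 400))
  for (par in list(c(1, 0.5), c(10, 0.5), c(3, 2.9), c(0.51, 0.5))) {
    g <- transfer_gain(grid, par[1], par[2])
    expect_equal(which.max(g), 1L)
  }
  expect_error(transfer_gain(0, 1, 1), class = "hetnetdyn_singular_error")
})

test_that("averaged gain: mixtures, closed-form uniform integral, quadrature", {
  # constant specs reduce to the plain gain
  expect_equal(averaged_gain(0.7, dist_constant(2), dist_constant(0.5)),
               transfer_gain(0.7, 2, 0.5))
  # two-term mixture at omega = 0
  expect_equal(averaged_gain(0, dist_two_point(0.5, 1, 10), dist_constant(0.5)),
               0.5 * 4 + 0.5 * (10 / 9.5)^2, tolerance = 1e-12)
  # closed-form integral of (gamma/(gamma-beta))^2 over beta ~ U[0, 2.9]
  expect_equal(averaged_gain(0, dist_constant(3), dist_uniform(0, 2.9)),
               (9 / 2.9) * (1 / 0.1 - 1 / 3), tolerance = 1e-9)
  # node-doubling convergence for a joint continuous spec
  g64 <- averaged_gain(0.4, dist_uniform(2, 6), dist_truncnorm(0.5, 0.3, 0, 1.5),
                       nodes = 64)
  g128 <- averaged_gain(0.4, dist_uniform(2, 6), dist_truncnorm(0.5, 0.3, 0, 1.5),
                        nodes = 128)
  expect_equal(g64, g128, tolerance = 1e-10)
  # Monte-Carlo oracle
  gd <- dist_uniform(2, 6)
  bd <- dist_truncnorm(0.5, 0.3, 0, 1.5)
  ga <- sample_params(gd, 1e5, seed = 2)
  be <- sample_params(bd, 1e5, seed = 3)
  vals <- transfer_gain(0.4, ga, be)
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(g64 - mean(vals)), 4 * se)
  # support touching gamma = beta diverges
  expect_error(averaged_gain(0, dist_constant(2), dist_uniform(0, 2)),
               class = "hetnetdyn_singular_error")
})

test_that("critical coupling: closed forms, limits, monotonicity, self-consistency", {
  # uniform feedback heterogeneity of the impulse-response study: 1/sqrt(30)
  cc <- critical_coupling(dist_constant(3), dist_uniform(0, 2.9))
  expect_equal(cc$gc, 1 / sqrt(30), tolerance = 1e-6)
  expect_equal(cc$omega_star, 0)
  expect_equal(cc$gc^2 * cc$gain_max, 1, tolerance = 1e-10)

  # homogeneous limits of the two-point expression
  expect_equal(critical_coupling_two_point(0, 1, 10, 0)$gc, 1)
  expect_equal(critical_coupling_two_point(0, 1, 1e9, 0.5)$gc, 1, tolerance = 1e-8)
  expect_equal(critical_coupling_two_point(0, 1, 10, 0.5)$gc, 0.95)
  expect_equal(critical_coupling_two_point(1, 1, 10, 0.5)$gc, 0.5)

  # strictly decreasing in the GPA fraction p
  ps <- seq(0, 1, by = 0.1)
  gcs <- vapply(ps, function(p) critical_coupling_two_point(p, 1, 5, 0.5)$gc,
                numeric(1))
  expect_true(all(diff(gcs) < 0))

  expect_error(critical_coupling_two_point(0.5, 5, 1, 0.5),
               class = "hetnetdyn_parameter_error")
  expect_error(critical_coupling_two_point(0.5, 1, 5, 1.2),
               class = "hetnetdyn_parameter_error")
})

test_that("general quadrature path agrees with the two-point closed form", {
  set.seed(20)
  for (i in 1:20) {
    beta <- runif(1, 0, 0.8)
    glow <- beta + runif(1, 0.1, 2)
    ghigh <- glow + runif(1, 0.5, 10)
    p <- runif(1)
    a <- critical_coupling_two_point(p, glow, ghigh, beta)
    b <- critical_coupling(dist_two_point(p, glow, ghigh), dist_constant(beta))
    expect_equal(b$gc, a$gc, tolerance = 1e-10)
  }
})

test_that("naive Gaussian-adaptation prediction: limit, monotonicity, breakdown", {
  # sigma = 0 reduces to the constant-beta theory
  g0 <- naive_critical_coupling(0.5, -0.5, 0)
  ref <- critical_coupling(dist_constant(0.5), dist_constant(-0.5))
  expect_equal(g0$gc, ref$gc, tolerance = 1e-8)
  # adaptation maximises the gain off zero frequency
  expect_gt(ref$omega_star, 0)
  # naive prediction is non-increasing in sigma_beta
  sig <- c(0, 0.2, 0.4, 0.6)
  ghat <- vapply(sig, function(s) naive_critical_coupling(0.5, -0.5, s)$gc,
                 numeric(1))
  expect_true(all(diff(ghat) <= 0))
  # denominator crossing zero is reported, not clipped
  expect_error(naive_critical_coupling(0.5, -0.5, 5),
               class = "hetnetdyn_naive_breakdown_error")
})

test_that("correct vs naive adaptation theories diverge in direction", {
  sig <- c(0.2, 0.6)
  gc <- vapply(sig, function(s) {
    critical_coupling(dist_constant(0.5),
                      dist_truncnorm(-0.5, s, -0.5 - 4 * s, -1e-3))$gc
  }, numeric(1))
  ghat <- vapply(sig, function(s) naive_critical_coupling(0.5, -0.5, s)$gc,
                 numeric(1))
  expect_gt(gc[2], gc[1])    # averaged-gain theory: transition moves up
  expect_lt(ghat[2], ghat[1]) # naive theory: transition moves down
})
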