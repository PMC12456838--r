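make_traj <- function(x, dt = 0.02) {
  structure(
    list(t0 = 0, dt = dt, times = dt * seq_len(nrow(x)), x = x, a = NULL,
         u = NULL, model_ref = list(N = ncol(x), g = 0, seed = 0,
                                    activation = "tanh")),
    class = "trajectory"
  )
}

test_that("PSD of a zero trajectory is identically zero", {
  tr <- make_traj(matrix(0, 4096, 3))
  sp <- estimate_psd(tr)
  expect_true(all(sp$psd_mean == 0))
  expect_equal(sp$max_power, 0)
})

test_that("a pure sinusoid concentrates power within one frequency bin", {
  dt <- 0.02
  om0 <- 2.5
  t <- dt * seq_len(8192)
  tr <- make_traj(matrix(sin(om0 * t), ncol = 1), dt)
  sp <- estimate_psd(tr, nfft = 2048)
  dom <- sp$omega[2] - sp$omega[1]
  expect_lt(abs(sp$omega[which.max(sp$psd_mean)] - om0), dom + 1e-12)
})

test_that("Parseval: integrated PSD recovers the series variance", {
  set.seed(3)
  x <- matrix(rnorm(3 * 8192), ncol = 3)
  sp <- estimate_psd(make_traj(x), nfft = 1024)
  dom <- sp$omega[2] - sp$omega[1]
  integral <- sum(sp$psd_mean) * dom
  expect_equal(integral, mean(apply(x, 2, stats::var)), tolerance = 0.05)
})

test_that("single linear neuron under white noise tracks its transfer gain", {
  m <- build_network(dist_constant(2), dist_constant(0.5), N = 1, g = 0, seed = 1)
  tr <- integrate_network(m, input_white_noise(0.1, 1), dt = 0.02,
                          T_total = 500, seed = 2, record = "x")
  sx <- estimate_psd(tr, t_min = 20, nfft = 2048)
  utr <- tr; utr$x <- matrix(tr$u / tr$dt, ncol = 1)
  su <- estimate_psd(utr, t_min = 20, nfft = 2048)
  band <- sx$omega >= 0.3 & sx$omega <= 3
  ratio <- sx$psd_mean[band] / su$psd_mean[band]
  expect_lt(max(abs(ratio / transfer_gain(sx$omega[band], 2, 0.5) - 1)), 0.1)
})

test_that("order parameter is invariant to neuron permutation and sign flip", {
  m <- small_net(N = 20, g = 1.5, seed = 4)
  tr <- hetnetdyn:::free_run(m, 60, 20, 0.02, 4)
  op <- estimate_psd(tr, t_min = 20, nfft = 512, demean = FALSE)$max_power
  tr2 <- tr; tr2$x <- -tr$x[, sample(20), drop = FALSE]
  op2 <- estimate_psd(tr2, t_min = 20, nfft = 512, demean = FALSE)$max_power
  expect_equal(op2, op, tolerance = 1e-12)
})

test_that("uncoupled stable network scores silent; trajectories too short error", {
  m <- small_net(N = 20, g = 0, seed = 5)
  ops <- hetnetdyn:::op_two_windows(m, T_run = 60, T_trans = 20, dt = 0.02,
                                    seed = 5, nfft = 512)
  thr <- silent_threshold(m, T_run = 60, T_trans = 20, seed = 5, nfft = 512)
  # decaying to the origin: shrinking across the window or below the floor
  expect_true(ops$final <= thr || ops$final < 0.2 * ops$first)
  tr <- make_traj(matrix(0, 100, 2))
  expect_error(estimate_psd(tr, nfft = 1024), class = "hetnetdyn_length_error")
})

test_that("phase diagram of a single cell reduces to the order-parameter run", {
  spec_fn <- function(p) two_point_spec(p, 1, 5, 0.5)
  pd <- phase_diagram(het = 0.5, g = 1.4, spec_fn, N = 60, seed = 2,
                      T_run = 60, T_trans = 20, nfft = 512)
  expect_equal(nrow(pd), 1L)
  expect_equal(pd$gc_analytic, critical_coupling_two_point(0.5, 1, 5, 0.5)$gc,
               tolerance = 1e-8)
  expect_true(pd$dynamic) # well above gc: sustained activity
})

test_that("white-noise series decorrelates within about one step", {
  set.seed(6)
  tr <- make_traj(matrix(rnorm(4000), ncol = 2))
  ac <- autocorrelation_summary(tr, max_lag_time = 1)
  expect_true(all(ac$correlation_times$corr_time <= 2 * tr$dt))
})

test_that("linear-neuron correlation time matches the 2x2 OU-process oracle", {
  skip_if_not_installed("Matrix")
  gamma <- 0.6; beta <- 0.5
  A <- matrix(c(-1, beta, 1, -gamma), 2, 2)
  # stationary covariance of dz = Az dt + noise in x: Lyapunov equation
  Q <- matrix(c(1, 0, 0, 0), 2, 2)
  K <- kronecker(A, diag(2)) + kronecker(diag(2), A)
  Sig <- matrix(solve(K, -as.vector(Q)), 2, 2)
  acf_x <- function(tau) (as.matrix(Matrix::expm(A * tau)) %*% Sig)[1, 1] / Sig[1, 1]
  tau_ref <- stats::uniroot(function(t) acf_x(t) - exp(-1), c(0.1, 60))$root

  m <- build_network(dist_constant(gamma), dist_constant(beta), N = 1, g = 0,
                     seed = 1)
  tr <- integrate_network(m, input_white_noise(0.2, 1), dt = 0.02,
                          T_total = 3000, seed = 3, record = "x")
  ac <- autocorrelation_summary(tr, max_lag_time = 60, t_min = 100)
  expect_equal(ac$correlation_times$corr_time[1], tau_ref, tolerance = 0.2)
})

test_that("zero-variance series get zero correlation time and a flag", {
  tr <- make_traj(cbind(rnorm(500), rep(1, 500)))
  ac <- autocorrelation_summary(tr)
  expect_true(ac$correlation_times$zero_variance[2])
  expect_equal(ac$correlation_times$corr_time[2], 0)
})

test_that("GPA and normal subgroups decorrelate similarly in the chaotic regime", {
  m <- build_network(dist_two_point(0.5, 1, 10), dist_constant(0.5),
                     N = 200, g = 2, seed = 7)
  tr <- hetnetdyn:::free_run(m, 150, 50, 0.02, 7)
  grp <- ifelse(m$population$gamma == 1, "gpa", "normal")
  ac <- autocorrelation_summary(tr, subgroups = grp, max_lag_time = 10,
                                t_min = 50)
  wide <- tidyr::pivot_wider(ac$acf_mean, names_from = "subgroup",
                             values_from = "acf")
  expect_lt(max(abs(wide$gpa - wide$normal)), 0.3)
})
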