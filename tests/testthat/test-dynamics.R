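test_that("the origin is a fixed point of the autonomous dynamics", {
  m <- small_net(N = 10, g = 0.8, seed = 1)
  tr <- integrate_network(m, T_total = 5)
  expect_true(all(tr$x == 0))
  expect_true(all(tr$a == 0))
})

test_that("uncoupled neuron matches the matrix-exponential solution, first order in dt", {
  skip_if_not_installed("Matrix")
  m <- build_network(dist_constant(2), dist_constant(0.5), N = 1, g = 0, seed = 1)
  ref <- linear_neuron_state(2, 0.5, c(1, 0), t = 1)
  err <- sapply(c(0.01, 0.005), function(dt) {
    tr <- integrate_network(m, x0 = 1, a0 = 0, dt = dt, T_total = 1)
    sqrt((tr$x[nrow(tr$x), 1] - ref[1])^2 + (tr$a[nrow(tr$a), 1] - ref[2])^2)
  })
  expect_lt(err[1], 0.01)
  expect_gt(err[1] / err[2], 1.7) # Euler: halving dt roughly halves the error
  expect_lt(err[1] / err[2], 2.3)
})

test_that("g = 0 networks are exactly a bank of independent linear neurons", {
  skip_if_not_installed("Matrix")
  m <- build_network(dist_two_point(0.5, 1, 10), dist_constant(0.5),
                     N = 6, g = 0, seed = 2)
  x0 <- seq(-1, 1, length.out = 6)
  tr <- integrate_network(m, x0 = x0, a0 = numeric(6), dt = 0.002, T_total = 2)
  for (i in 1:6) {
    ref <- linear_neuron_state(m$population$gamma[i], 0.5, c(x0[i], 0), t = 2)
    expect_equal(tr$x[nrow(tr$x), i], ref[1], tolerance = 5e-3)
  }
})

test_that("time-translation invariance without input", {
  m <- small_net(N = 15, g = 1.2, seed = 6)
  x0 <- sin(1:15)
  tr <- integrate_network(m, x0 = x0, dt = 0.02, T_total = 10)
  k <- 250 # restart from t = 5
  tr2 <- integrate_network(m, x0 = tr$x[k, ], a0 = tr$a[k, ], dt = 0.02,
                           T_total = 5, t0 = tr$times[k])
  expect_equal(tr2$x, tr$x[(k + 1):nrow(tr$x), ], tolerance = 1e-12)
})

test_that("graded-persistent vs normal neuron contrast under a pulse train", {
  pulses <- data.frame(t_start = 5, t_end = 7, amplitude = 1)
  # GPA neuron (slow auxiliary decay): plateau loses < 5% per unit time
  gpa <- single_neuron_pulse_response(0.51, 0.5, pulses, T_total = 17)
  x_off <- gpa$x[gpa$times > 7, 1]
  lvl1 <- x_off[sum(gpa$times[gpa$times > 7] <= 8)]
  lvl2 <- x_off[length(x_off)] # 9 units later
  expect_gt(lvl2 / lvl1, 0.95^9)
  # slow-mode rate for (gamma=0.51, beta=0.5) is ~0.00666 per unit time
  expect_equal(neuron_eigen(0.51, 0.5)[1], -0.0066515, tolerance = 1e-4)
  # normal neuron decays rapidly: its slowest mode is -0.945 per unit time,
  # so within 6 units of pulse offset the activity is below 1% of peak
  # (the GPA neuron above retains > 95% over a longer span)
  expect_equal(neuron_eigen(10, 0.5)[1], -0.945, tolerance = 1e-3)
  nrm <- single_neuron_pulse_response(10, 0.5, pulses, T_total = 13.5)
  peak <- max(nrm$x[, 1])
  expect_lt(abs(nrm$x[sum(nrm$times <= 13), 1]), 0.01 * peak)
})

test_that("plateau steps up after depolarizing and down after hyperpolarizing pulses", {
  fx <- fixture_suite(1)
  tr <- fx$trajectories$fig_gpa
  # sample the plateau 6 time units after each pulse ends
  lv <- sapply(fx$pulse_protocol$t_end, function(te) tr$x[sum(tr$times <= te + 6), 1])
  expect_true(all(diff(lv[1:3]) > 0)) # three depolarizing pulses
  expect_true(all(diff(lv[3:5]) < 0)) # two hyperpolarizing pulses
})

test_that("beta = 0 decouples the auxiliary variable", {
  pulses <- data.frame(t_start = 1, t_end = 2, amplitude = 1)
  tr <- single_neuron_pulse_response(3, 0, pulses, T_total = 6)
  expect_true(all(tr$a == 0))
  expect_gt(max(tr$x), 0)
})

test_that("divergence is detected and reported with a step index", {
  m <- build_network(dist_constant(0.2), dist_constant(0.5), N = 2, g = 0,
                     seed = 1, allow_unstable = TRUE)
  err <- tryCatch(
    integrate_network(m, x0 = c(1, 1), dt = 0.05, T_total = 200, guard = 1e3),
    error = function(e) e
  )
  expect_s3_class(err, "hetnetdyn_divergence_error")
  expect_true(is.numeric(err$step))
})

test_that("overlapping pulse intervals are rejected", {
  bad <- data.frame(t_start = c(1, 2), t_end = c(3, 4), amplitude = 1)
  expect_error(input_pulse_train(bad), class = "hetnetdyn_parameter_error")
})

test_that("impulse response profile: zero pulse, linear oracle, beta ordering", {
  skip_if_not_installed("Matrix")
  m <- small_net(N = 10, g = 0.1, seed = 3)
  pr0 <- impulse_response_experiment(m, amplitude = 0, T_total = 20)
  expect_true(all(pr0$amplitude == 0))

  # single linear neuron: peak matches the piecewise closed form
  m1 <- build_network(dist_constant(2), dist_constant(0.5), N = 1, g = 0, seed = 1)
  pr <- impulse_response_experiment(m1, amplitude = 1, t_on = 1, duration = 0.5,
                                    dt = 0.002, T_total = 10)
  z_end <- linear_neuron_state(2, 0.5, c(0, 0), t = 0.5, b = c(1, 0))
  ts <- seq(0, 9, by = 0.002)
  peak_ref <- max(abs(vapply(ts, function(t)
    linear_neuron_state(2, 0.5, z_end, t)[1], numeric(1))), abs(z_end[1]))
  expect_equal(pr$amplitude[1], peak_ref, tolerance = 5e-3)

  # heterogeneous beta: post-pulse decay time increases with beta
  net <- build_network(dist_constant(3), dist_uniform(0, 2.9), N = 100,
                       g = 0.15, seed = 8)
  prof <- impulse_response_experiment(net, amplitude = 1, t_on = 2,
                                      duration = 0.5, T_total = 50)
  ok <- !is.na(prof$decay_time)
  expect_gt(stats::cor(prof$beta[ok], prof$decay_time[ok], method = "spearman"), 0)
})
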