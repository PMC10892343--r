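quiet_cfg <- function(...) {
  synth_config(acc_noise_sd = 0, gyro_noise_sd = 0, mag_noise_sd = 0,
               gyro_bias = 0, timestamp_jitter_ms = 0, ...)
}

test_that("static simulation reproduces gravity and sample counts", {
  sim <- simulate_static(2, tilt_deg = c(0, 0, 0), cfg = quiet_cfg(seed = 65))
  a <- sim$streams$acc$values
  expect_equal(a, matrix(c(0, 0, 9.81), nrow(a), 3, byrow = TRUE),
               tolerance = 1e-9, ignore_attr = TRUE)
  # 2 s at 400 Hz, both endpoints on the grid
  expect_equal(nrow(a), 801)
  expect_equal(nrow(sim$streams$mag$values), 201)

  sim30 <- simulate_static(2, tilt_deg = c(30, 0, 0), cfg = quiet_cfg(seed = 65))
  g_s <- sim30$streams$acc$values[1, ]
  q <- euler_to_quat(30, 0, 0)
  expect_equal(g_s, frtkit:::quat_rotate_inv(q, c(0, 0, 9.81)),
               tolerance = 1e-12)
  expect_equal(sqrt(sum(g_s^2)), 9.81, tolerance = 1e-9)
})

test_that("trial generator: reach by construction, determinism, timing", {
  cfg <- synth_config(reach_m = 0.25, seed = 67)
  sim <- simulate_frt_trial(cfg)
  expect_equal(sim$truth$reach_cm, rep(25, cfg$n_attempts))
  expect_equal(length(sim$truth$attempt_centers_s), cfg$n_attempts)
  expect_equal(100 * max(sqrt(rowSums(sim$truth$position[, 1:2]^2))), 25,
               tolerance = 1e-6)

  sim2 <- simulate_frt_trial(synth_config(reach_m = 0.25, seed = 67))
  expect_identical(sim$streams$acc$values, sim2$streams$acc$values)
  expect_identical(sim$streams$gyr$t_ns, sim2$streams$gyr$t_ns)
  expect_identical(sim$streams$mag$values, sim2$streams$mag$values)

  sim3 <- simulate_frt_trial(synth_config(reach_m = 0.25, seed = 68))
  expect_false(identical(sim$streams$acc$values, sim3$streams$acc$values))
})

test_that("zero-motion trial keeps accelerometer magnitude at gravity", {
  # static portions of a noise-free trial: |a| = 9.81 throughout the quiet
  sim <- simulate_frt_trial(quiet_cfg(seed = 69))
  t <- stream_time(sim$streams$acc)
  mags <- sqrt(rowSums(sim$streams$acc$values^2))
  expect_equal(mags[t < 11], rep(9.81, sum(t < 11)), tolerance = 1e-9)
})

test_that("emitted gyroscope matches the orientation derivative", {
  cfg <- quiet_cfg(seed = 71, lean_duration_s = 1, pre_quiet_s = 1,
                   inter_quiet_s = 1, n_attempts = 1,
                   acc_rate = 2000, gyro_rate = 2000, truth_rate = 2000)
  sim <- simulate_frt_trial(cfg)
  q <- sim$truth$orientation
  g <- sim$streams$gyr$values
  dt <- 1 / cfg$truth_rate
  n <- nrow(q)
  worst <- 0
  for (i in seq(2, n - 1)) {
    # omega = 2 * vec(q_i^* (q_{i+1} - q_{i-1}) / (2 dt))
    dq <- (q[i + 1, ] - q[i - 1, ]) / (2 * dt)
    w_est <- 2 * quat_multiply(quat_conjugate(frtkit:::as_quat(q[i, ])),
                               frtkit:::as_quat(dq))[2:4]
    worst <- max(worst, max(abs(w_est - g[i, ])))
  }
  expect_lt(worst, 1e-6)
})

test_that("emitted accelerometer matches the position's second derivative", {
  cfg <- quiet_cfg(seed = 73, lean_duration_s = 1, pre_quiet_s = 1,
                   inter_quiet_s = 1, n_attempts = 1,
                   acc_rate = 2000, gyro_rate = 2000, truth_rate = 2000)
  sim <- simulate_frt_trial(cfg)
  p <- sim$truth$position
  q <- sim$truth$orientation
  a <- sim$streams$acc$values
  dt <- 1 / cfg$truth_rate
  n <- nrow(p)
  t <- sim$truth$t
  # the minimum-jerk profile has jerk steps at segment joins (t = 1, 2, 3 s
  # here), where a second difference is only first-order accurate; test the
  # smooth interior
  joins <- c(1, 2, 3)
  worst <- 0
  for (i in seq(2, n - 1, by = 7)) {
    if (min(abs(t[i] - joins)) < 3 * dt) next
    acc_e <- (p[i + 1, ] - 2 * p[i, ] + p[i - 1, ]) / dt^2
    a_s <- frtkit:::quat_rotate_inv(frtkit:::as_quat(q[i, ]),
                                    acc_e + c(0, 0, 9.81))
    worst <- max(worst, max(abs(a_s - a[i, ])))
  }
  expect_lt(worst, 1e-4)
})

test_that("noise-free magnetometer has constant norm", {
  sim <- simulate_frt_trial(quiet_cfg(seed = 75))
  norms <- sqrt(rowSums(sim$streams$mag$values^2))
  expect_equal(norms, rep(sqrt(22^2 + 40^2), length(norms)),
               tolerance = 1e-9)
})

test_that("configuration validation rejects impossible setups", {
  expect_error(synth_config(reach_m = 0), "reach_m")
  expect_error(synth_config(n_attempts = 0), "n_attempts")
  expect_error(synth_config(reach_m = 2, sensor_height_m = 1), "lever arm")
})
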