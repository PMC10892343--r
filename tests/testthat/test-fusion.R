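test_that("gyroscope propagation: rest, one hand-checked step, closed form", {
  q <- quat_normalize(quat(0.9, 0.1, -0.3, 0.2))
  expect_equal(as.numeric(gyro_propagate(q, c(0, 0, 0), 0.01)),
               as.numeric(q), tolerance = 1e-12)

  # one step from identity: q + 0.5 * (0, 0, 0, 0.1) * 0.01, then normalized
  stepped <- gyro_propagate(quat(1, 0, 0, 0), c(0, 0, 0.1), 0.01)
  expect_equal(as.numeric(stepped),
               c(1, 0, 0, 5e-4) / sqrt(1 + 5e-4^2), tolerance = 1e-12)

  # 1000 steps at pi/2 rad/s for 1 s: 90 degrees about z
  q <- quat(1, 0, 0, 0)
  for (i in 1:1000) q <- gyro_propagate(q, c(0, 0, pi / 2), 1e-3)
  expect_lt(quat_angle(q, quat_from_axis_angle(c(0, 0, 1), pi / 2)), 1e-4)

  expect_error(gyro_propagate(quat(1, 0, 0, 0), c(0, 0, 1), 0), "dt")
})

test_that("quaternion-derivative and Omega-matrix propagation agree", {
  set.seed(21)
  for (i in 1:100) {
    q <- random_unit_quat()
    w <- rnorm(3); dt <- runif(1, 1e-4, 1e-2)
    expect_equal(as.numeric(gyro_propagate(q, w, dt)),
                 omega_propagate(q, w, dt), tolerance = 1e-12)
  }
})

test_that("gradient objective: aligned, rotated and hand-computed cases", {
  expect_equal(madgwick_objective(quat(1, 0, 0, 0), c(0, 0, 1), c(0, 0, 1)),
               c(0, 0, 0))
  s <- sqrt(0.5)
  # 90 deg about x maps sensor y to Earth z, so gravity measured on +y
  expect_equal(madgwick_objective(quat(s, s, 0, 0), c(0, 0, 1), c(0, 1, 0)),
               c(0, 0, 0), tolerance = 1e-12)
  expect_equal(madgwick_objective(quat(1, 0, 0, 0), c(0, 0, 1), c(1, 0, 0)),
               c(-1, 0, 1))
  expect_error(madgwick_objective(quat(1, 0, 0, 0), c(0, 0, 1), c(0, 0, 0)),
               "zero")
})

test_that("magnetic reference collapses to horizontal-plus-vertical form", {
  # identity rotation: h equals the normalized measurement (3,4,5)
  b <- magnetic_reference(quat(1, 0, 0, 0), c(3, 4, 5))
  expect_equal(b, c(5, 0, 5) / sqrt(50), tolerance = 1e-12)

  # identity rotation, field along Earth y with downward dip
  b2 <- magnetic_reference(quat(1, 0, 0, 0), c(0, 22, -40))
  expect_equal(b2, c(22, 0, -40) / sqrt(22^2 + 40^2), tolerance = 1e-12)

  set.seed(23)
  for (i in 1:50) {
    b <- magnetic_reference(quat_normalize(quat(rnorm(1), rnorm(1), rnorm(1),
                                                rnorm(1))), rnorm(3))
    expect_identical(b[2], 0)
    expect_equal(sqrt(sum(b^2)), 1, tolerance = 1e-12)
  }
  expect_error(magnetic_reference(quat(1, 0, 0, 0), c(0, 0, 0)), "zero")
})

test_that("analytic Jacobian matches numerical differentiation", {
  set.seed(27)
  for (i in 1:30) {
    q <- random_unit_quat()
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    J <- frtkit:::objective_jacobian(q, d)
    eps <- 1e-7
    for (k in 1:4) {
      qp <- q; qp[k] <- qp[k] + eps
      qm <- q; qm[k] <- qm[k] - eps
      num <- (frtkit:::quat_rotate_inv(qp, d) -
              frtkit:::quat_rotate_inv(qm, d)) / (2 * eps)
      expect_equal(J[, k], num, tolerance = 1e-5)
    }
  }
})

test_that("static gravity-aligned input is a fixed point of the fused step", {
  cfg <- ahrs_config(0.01, beta = 0.5)
  q <- quat(1, 0, 0, 0)
  for (i in 1:20)
    q <- madgwick_update(q, c(0, 0, 0), c(0, 0, 9.81), NULL, cfg)
  expect_equal(as.numeric(q), c(1, 0, 0, 0), tolerance = 1e-9)
})

test_that("zero fusion gain reduces the filter to pure gyro integration", {
  set.seed(29)
  n <- 200
  gyr <- matrix(rnorm(3 * n, 0, 0.5), n, 3)
  acc <- matrix(rnorm(3 * n, 0, 1), n, 3) +
    matrix(c(0, 0, 9.81), n, 3, byrow = TRUE)
  cfg <- ahrs_config(0.01, beta = 0)
  qm <- run_ahrs(acc, gyr, NULL, cfg)
  q <- quat(1, 0, 0, 0)
  for (i in 1:n) {
    q <- gyro_propagate(q, gyr[i, ], 0.01)
    expect_equal(qm[i, ], as.numeric(q), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("filter output stays unit norm and handles aligned static input", {
  n <- 300
  acc <- matrix(c(0, 0, 9.81), n, 3, byrow = TRUE)
  gyr <- matrix(0, n, 3)
  qm <- run_ahrs(acc, gyr, NULL, ahrs_config(0.01, beta = 0.3))
  expect_true(all(abs(sqrt(rowSums(qm^2)) - 1) < 1e-9))
  expect_true(all(abs(qm[, 1] - 1) < 1e-9))
  expect_error(run_ahrs(acc, gyr[1:10, ], NULL, ahrs_config(0.01)),
               "lengths differ")
})

test_that("tilted static orientation is recovered below 0.1 degree", {
  cfg <- synth_config(acc_noise_sd = 0, gyro_noise_sd = 0, mag_noise_sd = 0,
                      gyro_bias = 0, timestamp_jitter_ms = 0, seed = 31)
  sim <- simulate_static(8, tilt_deg = c(25, -15, 60), cfg = cfg)
  al <- align_streams(sim$streams$acc, sim$streams$gyr, sim$streams$mag, 100)
  n <- nrow(al$accel); half <- n %/% 2
  # converge at a high gain, then settle at a low one: the normalized
  # gradient step dithers in a limit cycle of amplitude ~beta*dt, so the
  # settled accuracy is read out at small beta
  q1 <- run_ahrs(al$accel[1:half, ], al$gyro[1:half, ], al$mag[1:half, ],
                 ahrs_config(0.01, beta = 1))
  qm <- run_ahrs(al$accel[(half + 1):n, ], al$gyro[(half + 1):n, ],
                 al$mag[(half + 1):n, ],
                 ahrs_config(0.01, beta = 0.02, initial_q = q1[half, ]))
  est <- quat_to_euler(qm[nrow(qm), ])
  truth <- quat_to_euler(sim$truth$orientation[1, ])
  expect_lt(abs(est[1] - truth[1]), 0.1)       # roll
  expect_lt(abs(est[2] - truth[2]), 0.1)       # pitch
})

test_that("fused filter matches the independent Omega/numeric-gradient oracle", {
  cfg <- synth_config(seed = 33)               # default noise levels
  sim <- simulate_static(10, tilt_deg = c(15, 10, -40), cfg = cfg)
  al <- align_streams(sim$streams$acc, sim$streams$gyr, sim$streams$mag, 100)
  beta <- 0.1
  qm <- run_ahrs(al$accel, al$gyro, al$mag,
                 ahrs_config(0.01, beta = beta))
  q <- c(1, 0, 0, 0)
  worst <- 0
  for (i in seq_len(nrow(al$accel))) {
    q <- oracle_madgwick_step(q, al$gyro[i, ], al$accel[i, ], al$mag[i, ],
                              beta, 0.01)
    worst <- max(worst, quat_angle(qm[i, ], q) * 180 / pi)
  }
  expect_lt(worst, 0.5)
})

test_that("magnetometer fusion improves heading on the same stream", {
  cfg <- synth_config(seed = 35)
  sim <- simulate_static(20, tilt_deg = c(10, 5, 45), cfg = cfg)
  al <- align_streams(sim$streams$acc, sim$streams$gyr, sim$streams$mag, 100)
  truth_e <- quat_series_to_euler(
    sim$truth$orientation[seq_len(nrow(al$accel)), , drop = FALSE])
  keep <- al$t >= 5
  run_one <- function(usemag) {
    qm <- run_ahrs(al$accel, al$gyro, if (usemag) al$mag,
                   ahrs_config(0.01, beta = 0.5, use_magnetometer = usemag))
    est_e <- quat_series_to_euler(qm[keep, , drop = FALSE])
    benchmark_orientation(est_e, truth_e[keep, , drop = FALSE],
                          yaw_offset = 90)["yaw", "rmse"]
  }
  expect_lt(run_one(TRUE), run_one(FALSE))
})

test_that("orientation initializer matches truth for static poses", {
  cfg <- synth_config(acc_noise_sd = 0, gyro_noise_sd = 0, mag_noise_sd = 0,
                      gyro_bias = 0, timestamp_jitter_ms = 0, seed = 37)
  sim <- simulate_static(2, tilt_deg = c(30, -20, 0), cfg = cfg)
  q0 <- ahrs_init_orientation(sim$streams$acc$values[1, ],
                              sim$streams$mag$values[1, ])
  e0 <- quat_to_euler(q0)
  truth <- quat_to_euler(sim$truth$orientation[1, ])
  expect_equal(unname(e0[1:2]), unname(truth[1:2]), tolerance = 1e-6)
})
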