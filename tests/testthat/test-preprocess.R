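make_stream <- function(t, vals, kind = "accelerometer", rate = NA_real_) {
  sensor_stream(kind, t_ns = t * 1e9, values = vals, rate = rate)
}

test_that("stream construction validates timestamps and shapes", {
  expect_error(make_stream(c(0, 0.01, 0.01), matrix(0, 3, 3)),
               "index 3")
  expect_error(make_stream(c(0, 0.01), matrix(0, 2, 4)), "3 value columns")
  s <- make_stream(c(0, 0.01, 0.02), matrix(1:9, 3, 3))
  expect_s3_class(s, "sensor_stream")
  expect_equal(s$units, "m/s^2")
})

test_that("resampling is idempotent on an already-uniform stream", {
  t <- (0:499) / 100
  vals <- cbind(sin(t), cos(2 * t), t)
  s <- make_stream(t, vals)
  r <- resample_uniform(s, 100)
  expect_equal(nrow(r$values), 500)
  expect_equal(r$values, vals, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("cubic splines recover smooth signals through timestamp jitter", {
  set.seed(41)
  t <- (0:999) / 100
  tj <- t; tj[2:999] <- tj[2:999] + runif(998, -1e-3, 1e-3)
  vals <- cbind(2 * tj + 1, -0.5 * tj + 3, tj^3 - tj)
  r <- resample_uniform(make_stream(tj, vals), 100)
  tg <- stream_time(r)
  expect_equal(r$values[, 1], 2 * tg + 1, tolerance = 1e-9)
  expect_equal(r$values[, 2], -0.5 * tg + 3, tolerance = 1e-9)
  expect_equal(r$values[, 3], tg^3 - tg, tolerance = 1e-7)
})

test_that("a 10 s stream resampled at 100 Hz yields 1001 samples", {
  set.seed(43)
  t <- seq(0, 10, by = 5e-3)
  t[2:(length(t) - 1)] <- t[2:(length(t) - 1)] +
    runif(length(t) - 2, -1e-3, 1e-3)
  r <- resample_uniform(make_stream(t, matrix(rnorm(3 * length(t)),
                                              ncol = 3)), 100)
  expect_equal(nrow(r$values), 1001)
  expect_equal(diff(stream_time(r)), rep(0.01, 1000), tolerance = 1e-12)
})

test_that("gravity filter rejects DC and passes the movement band", {
  n <- 5000
  t <- (0:(n - 1)) / 100
  vals <- cbind(rep(9.81, n), sin(2 * pi * 5 * t), 3 + sin(2 * pi * 3 * t))
  f <- highpass_gravity(make_stream(t, vals, rate = 100))
  mid <- 1500:3500
  expect_lt(max(abs(f$values[mid, 1])), 0.01)            # DC rejection
  expect_equal(max(abs(f$values[mid, 2])), 1, tolerance = 0.02)
  expect_equal(f$values[mid, 3], sin(2 * pi * 3 * t[mid]),
               tolerance = 0.02)                          # linearity in use
  expect_identical(f$t_ns, (t * 1e9))                     # aligned output
})

test_that("gravity filtering is linear", {
  set.seed(47)
  n <- 4000
  x <- matrix(rnorm(n), ncol = 1); y <- matrix(rnorm(n), ncol = 1)
  s <- function(v) make_stream((0:(n - 1)) / 100, cbind(v, v, v), rate = 100)
  fx <- highpass_gravity(s(x))$values[, 1]
  fy <- highpass_gravity(s(y))$values[, 1]
  fxy <- highpass_gravity(s(2.5 * x + y))$values[, 1]
  expect_equal(fxy, 2.5 * fx + fy, tolerance = 1e-9)
})

test_that("gravity filter refuses streams shorter than its order", {
  s <- make_stream((0:499) / 100, matrix(0, 500, 3), rate = 100)
  expect_error(highpass_gravity(s), "order")
})

test_that("movement detector: quiescence, single burst placement, two bursts", {
  n <- 7001
  t <- (0:(n - 1)) / 100
  quiet <- make_stream(t, matrix(rnorm(3 * n, 0, 1e-4), ncol = 3),
                       rate = 100)
  set.seed(49)
  expect_equal(nrow(detect_movement_windows(quiet)), 0)

  burst <- function(center, width = 1.5)
    ifelse(abs(t - center) < width,
           sin(2 * pi * 2 * (t - center)) * exp(-((t - center) / 0.8)^2), 0)
  one <- make_stream(t, cbind(burst(52.5), 0 * t, 0 * t), rate = 100)
  w <- detect_movement_windows(one)
  expect_equal(nrow(w), 1)
  expect_equal(w$start, 50, tolerance = 0.1)
  expect_equal(w$end, 55, tolerance = 0.1)
  expect_equal(w$end - w$start, 5, tolerance = 1e-9)
  expect_false(w$clipped)

  two <- make_stream(t, cbind(burst(20) + burst(40), 0 * t, 0 * t),
                     rate = 100)
  w2 <- detect_movement_windows(two)
  expect_equal(nrow(w2), 2)
  expect_equal(w2$center, c(20, 40), tolerance = 0.1)
  expect_true(all(abs(w2$end - w2$start - 5) < 1e-9))
  expect_lt(w2$end[1], w2$start[2])   # disjoint
})

test_that("windows at the recording edge are clipped and flagged", {
  n <- 2001
  t <- (0:(n - 1)) / 100
  b <- ifelse(abs(t - 1.5) < 1, sin(2 * pi * 2 * t), 0)
  w <- detect_movement_windows(make_stream(t, cbind(b, 0 * t, 0 * t),
                                           rate = 100))
  expect_true(nrow(w) >= 1)
  expect_true(w$clipped[1])
  expect_gte(w$start[1], 0)
})

test_that("alignment resamples fast streams and holds the magnetometer", {
  cfg <- synth_config(acc_noise_sd = 0, gyro_noise_sd = 0, mag_noise_sd = 0,
                      gyro_bias = 0, seed = 51)
  sim <- simulate_static(4, tilt_deg = c(5, 5, 0), cfg = cfg)
  al <- align_streams(sim$streams$acc, sim$streams$gyr, sim$streams$mag,
                      rate = 100)
  expect_equal(nrow(al$accel), nrow(al$gyro))
  expect_equal(nrow(al$accel), nrow(al$mag))
  expect_equal(diff(al$t), rep(0.01, length(al$t) - 1), tolerance = 1e-12)
  # sample-and-hold: every aligned magnetometer value is an original sample
  orig <- unique(round(sim$streams$mag$values[, 1], 9))
  expect_true(all(round(al$mag[, 1], 9) %in% orig))
})
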