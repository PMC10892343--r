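#' Configuration for the synthetic FRT MARG simulator
#'
#' Defaults emulate a smartphone strapped to the upper arm during a
#' functional reach test: 400 Hz accelerometer/gyroscope and 100 Hz
#' magnetometer with ~1 ms timestamp jitter, modest consumer-grade sensor
#' noise, and a hip-hinge lean-and-return movement of known horizontal
#' extent.
#'
#' @param reach_m true horizontal reach per attempt, metres.
#' @param lean_duration_s duration of each extension (and of each return),
#'   seconds.
#' @param n_attempts number of consecutive reach attempts.
#' @param pre_quiet_s quiet standing before the first attempt, seconds.
#' @param inter_quiet_s quiet interval between attempts and after the last
#'   one, seconds.
#' @param sensor_height_m lever arm from the hip pivot to the sensor, metres.
#' @param heading_deg reach direction, degrees counter-clockwise from east.
#' @param acc_rate,gyro_rate,mag_rate nominal sampling rates, Hz.
#' @param truth_rate rate of the emitted ground-truth series, Hz (matched to
#'   the pipeline's resampling grid by default).
#' @param timestamp_jitter_ms half-width of the uniform timestamp jitter,
#'   milliseconds; first and last samples stay on the nominal grid so the
#'   record span is exact.
#' @param acc_noise_sd,gyro_noise_sd,mag_noise_sd white noise standard
#'   deviations (m/s^2, rad/s, microtesla).
#' @param gyro_bias constant gyroscope bias, rad/s (applied to each axis
#'   scaled by \code{c(1, -0.5, 0.25)} so axes differ).
#' @param mag_field Earth magnetic field as \code{c(horizontal, vertical)}
#'   in microtesla; horizontal points geomagnetic north (ENU +y), vertical
#'   is signed along ENU +z (negative = downward dip).
#' @param seed integer seed making the generated streams reproducible.
#' @return object of class \code{"synth_config"}.
#' @export
synth_config <- function(reach_m = 0.20, lean_duration_s = 2, n_attempts = 2,
                         pre_quiet_s = 12, inter_quiet_s = 15,
                         sensor_height_m = 1.2, heading_deg = 0,
                         acc_rate = 400, gyro_rate = 400, mag_rate = 100,
                         truth_rate = 100, timestamp_jitter_ms = 1,
                         acc_noise_sd = 0.05, gyro_noise_sd = 0.005,
                         mag_noise_sd = 0.5, gyro_bias = 0.01,
                         mag_field = c(22, -40), seed = 1L) {
  if (reach_m <= 0) stop("reach_m must be > 0")
  if (n_attempts < 1) stop("n_attempts must be >= 1")
  if (any(c(acc_rate, gyro_rate, mag_rate, truth_rate) <= 0))
    stop("rates must be > 0")
  if (reach_m > sensor_height_m)
    stop("reach_m cannot exceed the sensor lever arm")
  structure(as.list(environment()), class = "synth_config")
}

# minimum-jerk unit profile and derivatives on tau in [0,1]
minjerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)
minjerk_d1 <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
minjerk_d2 <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3

# lean angle alpha(t) and time derivatives for the attempt schedule
lean_profile <- function(t, cfg, alpha_max) {
  a <- numeric(length(t)); ad <- a; add <- a
  Tl <- cfg$lean_duration_s
  for (k in seq_len(cfg$n_attempts)) {
    t0 <- cfg$pre_quiet_s + (k - 1) * (2 * Tl + cfg$inter_quiet_s)
    # extension
    in1 <- t >= t0 & t < t0 + Tl
    tau <- (t[in1] - t0) / Tl
    a[in1] <- alpha_max * minjerk(tau)
    ad[in1] <- alpha_max * minjerk_d1(tau) / Tl
    add[in1] <- alpha_max * minjerk_d2(tau) / Tl^2
    # return
    in2 <- t >= t0 + Tl & t < t0 + 2 * Tl
    tau <- (t[in2] - t0 - Tl) / Tl
    a[in2] <- alpha_max * (1 - minjerk(tau))
    ad[in2] <- -alpha_max * minjerk_d1(tau) / Tl
    add[in2] <- -alpha_max * minjerk_d2(tau) / Tl^2
  }
  list(a = a, ad = ad, add = add)
}

synth_total_duration <- function(cfg) {
  cfg$pre_quiet_s +
    cfg$n_attempts * 2 * cfg$lean_duration_s +
    cfg$n_attempts * cfg$inter_quiet_s
}

# jittered strictly-increasing timestamps with exact endpoints, seconds
jitter_times <- function(duration, rate, jitter_ms) {
  n <- round(duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  if (jitter_ms > 0 && n > 2) {
    j <- stats::runif(n - 2L, -jitter_ms / 1e3, jitter_ms / 1e3)
    j <- pmax(pmin(j, 0.49 / rate), -0.49 / rate)  # keep monotone
    t[2:(n - 1L)] <- t[2:(n - 1L)] + j
  }
  t
}

# evaluate the noise-free trial model at arbitrary times
synth_model_at <- function(t, cfg, alpha_max) {
  pr <- lean_profile(t, cfg, alpha_max)
  g <- cfg$heading_deg * pi / 180
  h <- c(cos(g), sin(g), 0)             # reach direction in XOY
  axis <- c(sin(g), -cos(g), 0)         # lean axis (top tips toward h)
  L <- cfg$sensor_height_m
  n <- length(t)
  qmat <- matrix(0, n, 4); pos <- matrix(0, n, 3)
  acc_s <- matrix(0, n, 3); gyr_s <- matrix(0, n, 3); mag_s <- matrix(0, n, 3)
  b_e <- c(0, cfg$mag_field[1], cfg$mag_field[2])
  for (i in seq_len(n)) {
    al <- pr$a[i]
    q <- quat_from_axis_angle(axis, al)
    qmat[i, ] <- q
    pos[i, ] <- L * (sin(al) * h + cos(al) * c(0, 0, 1)) - c(0, 0, L)
    acc_e <- L * ((pr$add[i] * cos(al) - pr$ad[i]^2 * sin(al)) * h -
                  (pr$add[i] * sin(al) + pr$ad[i]^2 * cos(al)) * c(0, 0, 1))
    acc_s[i, ] <- quat_rotate_inv(q, acc_e + c(0, 0, GRAVITY_MS2))
    gyr_s[i, ] <- pr$ad[i] * axis       # fixed axis: body rate = alpha' axis
    mag_s[i, ] <- quat_rotate_inv(q, b_e)
  }
  list(q = qmat, pos = pos, acc_s = acc_s, gyr_s = gyr_s, mag_s = mag_s)
}

#' Simulate a synthetic FRT trial with ground truth
#'
#' Hip-hinge kinematic model: a minimum-jerk lean-angle profile rotates a
#' lever arm of \code{sensor_height_m} about a horizontal axis, producing a
#' lean-and-return movement whose maximal horizontal excursion equals
#' \code{reach_m} exactly.  Sensor-frame accelerometer (specific force),
#' gyroscope (body rates plus bias) and magnetometer streams are sampled on
#' jittered timestamps with additive white noise; ground truth orientation
#' and position are emitted on a uniform grid at \code{truth_rate}.
#'
#' @param cfg \code{\link{synth_config}}.
#' @return list with \code{streams} (named list of
#'   \code{\link{sensor_stream}}: acc, gyr, mag) and \code{truth} (list:
#'   \code{t}, \code{orientation} n x 4, \code{position} n x 3,
#'   \code{reach_cm} per attempt, \code{attempt_centers_s}).
#' @export
simulate_frt_trial <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  alpha_max <- asin(cfg$reach_m / cfg$sensor_height_m)
  dur <- synth_total_duration(cfg)
  t_acc <- jitter_times(dur, cfg$acc_rate, cfg$timestamp_jitter_ms)
  t_gyr <- jitter_times(dur, cfg$gyro_rate, cfg$timestamp_jitter_ms)
  t_mag <- jitter_times(dur, cfg$mag_rate, cfg$timestamp_jitter_ms)

  macc <- synth_model_at(t_acc, cfg, alpha_max)
  mgyr <- synth_model_at(t_gyr, cfg, alpha_max)
  mmag <- synth_model_at(t_mag, cfg, alpha_max)

  na <- length(t_acc); ng <- length(t_gyr); nm <- length(t_mag)
  bias <- cfg$gyro_bias * c(1, -0.5, 0.25)
  acc_v <- macc$acc_s + matrix(stats::rnorm(3 * na, 0, cfg$acc_noise_sd), na, 3)
  gyr_v <- mgyr$gyr_s + matrix(bias, ng, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * ng, 0, cfg$gyro_noise_sd), ng, 3)
  mag_v <- mmag$mag_s + matrix(stats::rnorm(3 * nm, 0, cfg$mag_noise_sd), nm, 3)

  t_truth <- seq(0, dur, by = 1 / cfg$truth_rate)
  mt <- synth_model_at(t_truth, cfg, alpha_max)
  centers <- cfg$pre_quiet_s + (seq_len(cfg$n_attempts) - 1) *
    (2 * cfg$lean_duration_s + cfg$inter_quiet_s) + cfg$lean_duration_s

  grav_s <- t(vapply(seq_len(na), function(i)
    quat_rotate_inv(macc$q[i, ], c(0, 0, GRAVITY_MS2)), numeric(3)))
  rot_v <- cbind(mt$q[, 2:4], mt$q[, 1])   # X,Y,Z vector part, then scalar

  list(
    streams = list(
      acc = sensor_stream("accelerometer", t_ns = t_acc * 1e9, values = acc_v),
      gyr = sensor_stream("gyroscope", t_ns = t_gyr * 1e9, values = gyr_v),
      mag = sensor_stream("magnetometer", t_ns = t_mag * 1e9, values = mag_v),
      gra = sensor_stream("gravity", t_ns = t_acc * 1e9, values = grav_s),
      lin = sensor_stream("linear_acceleration", t_ns = t_acc * 1e9,
                          values = macc$acc_s - grav_s),
      rot = sensor_stream("rotation_vector", t_ns = t_truth * 1e9,
                          values = rot_v)
    ),
    truth = list(
      t = t_truth, orientation = mt$q, position = mt$pos,
      reach_cm = rep(100 * cfg$reach_m, cfg$n_attempts),
      attempt_centers_s = centers,
      config = cfg
    )
  )
}

#' Simulate a static (constant-orientation) MARG recording
#'
#' The sensor holds a fixed tilt; streams carry only the configured noise.
#' Useful for convergence and steady-state accuracy experiments.
#'
#' @param duration_s recording length, seconds.
#' @param tilt_deg constant orientation as \code{c(roll, pitch, yaw)} degrees.
#' @param cfg \code{\link{synth_config}} (noise, rates, field, seed).
#' @return same structure as \code{\link{simulate_frt_trial}}.
#' @export
simulate_static <- function(duration_s = 30, tilt_deg = c(0, 0, 0),
                            cfg = synth_config()) {
  set.seed(cfg$seed)
  q <- euler_to_quat(tilt_deg[1], tilt_deg[2], tilt_deg[3])
  b_e <- c(0, cfg$mag_field[1], cfg$mag_field[2])
  g_s <- quat_rotate_inv(q, c(0, 0, GRAVITY_MS2))
  m_s <- quat_rotate_inv(q, b_e)
  t_acc <- jitter_times(duration_s, cfg$acc_rate, cfg$timestamp_jitter_ms)
  t_gyr <- jitter_times(duration_s, cfg$gyro_rate, cfg$timestamp_jitter_ms)
  t_mag <- jitter_times(duration_s, cfg$mag_rate, cfg$timestamp_jitter_ms)
  na <- length(t_acc); ng <- length(t_gyr); nm <- length(t_mag)
  bias <- cfg$gyro_bias * c(1, -0.5, 0.25)
  acc_v <- matrix(g_s, na, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * na, 0, cfg$acc_noise_sd), na, 3)
  gyr_v <- matrix(bias, ng, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * ng, 0, cfg$gyro_noise_sd), ng, 3)
  mag_v <- matrix(m_s, nm, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * nm, 0, cfg$mag_noise_sd), nm, 3)
  t_truth <- seq(0, duration_s, by = 1 / cfg$truth_rate)
  nt <- length(t_truth)
  qn <- as.numeric(q)
  list(
    streams = list(
      acc = sensor_stream("accelerometer", t_ns = t_acc * 1e9, values = acc_v),
      gyr = sensor_stream("gyroscope", t_ns = t_gyr * 1e9, values = gyr_v),
      mag = sensor_stream("magnetometer", t_ns = t_mag * 1e9, values = mag_v),
      gra = sensor_stream("gravity", t_ns = t_acc * 1e9,
                          values = matrix(g_s, na, 3, byrow = TRUE)),
      lin = sensor_stream("linear_acceleration", t_ns = t_acc * 1e9,
                          values = matrix(0, na, 3)),
      rot = sensor_stream("rotation_vector", t_ns = t_truth * 1e9,
                          values = matrix(c(qn[2:4], qn[1]), nt, 4,
                                          byrow = TRUE))
    ),
    truth = list(
      t = t_truth,
      orientation = matrix(as.numeric(q), nt, 4, byrow = TRUE),
      position = matrix(0, nt, 3),
      reach_cm = numeric(0), attempt_centers_s = numeric(0),
      config = cfg
    )
  )
}
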