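#' AHRS fusion configuration
#'
#' @param sample_period sampling period in seconds (> 0).
#' @param beta fusion gain weighting the normalized gradient correction
#'   against gyroscope propagation, in rad/s of correction capacity.  The
#'   default 0.1 favours gyroscope dynamics; larger values converge faster
#'   from a wrong initial orientation at the price of more accelerometer
#'   noise feed-through (the initial convergence rate is about
#'   \code{2 * beta} rad/s).
#' @param use_magnetometer if \code{TRUE} and magnetometer samples are
#'   supplied, the Earth magnetic field is fused for heading correction.
#' @param initial_q initial orientation quaternion (default identity).
#' @return object of class \code{"ahrs_config"}.
#' @export
ahrs_config <- function(sample_period, beta = 0.1, use_magnetometer = TRUE,
                        initial_q = quat(1, 0, 0, 0)) {
  if (sample_period <= 0) stop("sample_period must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(sample_period = sample_period, beta = beta,
                 use_magnetometer = isTRUE(use_magnetometer),
                 initial_q = as_quat(initial_q)),
            class = "ahrs_config")
}

#' Propagate orientation one step from gyroscope rates
#'
#' Numerically integrates the quaternion kinematic equation
#' \code{dq/dt = 1/2 q (0, omega)} with an explicit Euler step and
#' renormalizes.  Equivalent (exactly, per step) to the additive
#' Omega-matrix form \code{q + 1/2 Omega(omega) q dt}.
#'
#' @param q_prev previous unit quaternion.
#' @param omega gyroscope rates, rad/s, sensor frame, length 3.
#' @param dt time step in seconds (> 0).
#' @return unit quaternion at the next sample.
#' @export
gyro_propagate <- function(q_prev, omega, dt) {
  if (dt <= 0) stop("dt must be > 0")
  qdot <- quat_multiply(q_prev, quat(0, omega[1], omega[2], omega[3]))
  quat_normalize(q_prev + 0.5 * unclass(qdot) * dt)
}

#' Gradient-descent objective for one reference direction
#'
#' Error between a known Earth-frame reference direction \code{d} brought
#' into the sensor frame by the current orientation estimate and the
#' normalized sensor measurement \code{s}:
#' \code{f = vec(q* (0,d) q) - s}.  The fusion step drives this to zero.
#'
#' @param q unit quaternion (sensor to Earth).
#' @param d Earth-frame reference direction, length 3, unit norm.
#' @param s measured direction in the sensor frame, length 3; normalized
#'   internally, zero-norm input is an error.
#' @return length-3 residual.
#' @export
madgwick_objective <- function(q, d, s) {
  ns <- sqrt(sum(s^2))
  if (ns < 1e-12) stop("zero-norm measurement cannot constrain orientation")
  quat_rotate_inv(q, d) - s / ns
}

# Analytic Jacobian of vec(q* (0,d) q) with respect to (w, x, y, z).
# With u the vector part: R(q)^T d = (w^2 - u.u) d + 2 (u.d) u - 2 w (u x d).
objective_jacobian <- function(q, d) {
  w <- q[1]; u <- q[2:4]
  J <- matrix(0, 3, 4)
  J[, 1] <- 2 * w * d - 2 * cross3(u, d)
  for (k in 1:3) {
    ek <- c(0, 0, 0); ek[k] <- 1
    J[, k + 1] <- -2 * u[k] * d + 2 * d[k] * u + 2 * sum(u * d) * ek -
      2 * w * cross3(ek, d)
  }
  J
}

#' Earth magnetic field reference from a magnetometer sample
#'
#' Rotates the normalized magnetometer reading into the Earth frame with the
#' previous orientation estimate and collapses it to a two-component
#' reference \code{(bx, 0, bz)} (horizontal magnitude and vertical
#' component), which makes the heading correction insensitive to soft-iron
#' distortion of the horizontal field direction.
#'
#' @param q_prev previous orientation estimate (unit quaternion).
#' @param m magnetometer sample, microtesla, length 3, nonzero.
#' @return unit-norm Earth-frame reference direction \code{c(bx, 0, bz)}.
#' @export
magnetic_reference <- function(q_prev, m) {
  nm <- sqrt(sum(m^2))
  if (nm < 1e-12) stop("zero magnetometer sample")
  h <- quat_rotate(q_prev, m / nm)
  b <- c(sqrt(h[1]^2 + h[2]^2), 0, h[3])
  b / sqrt(sum(b^2))
}

GRAVITY_REF <- c(0, 0, 1)   # ENU: z up

#' One fused orientation update (gradient-descent MARG filter)
#'
#' Combines one gyroscope propagation step with one normalized-gradient
#' correction step of the stacked gravity (and, if available, magnetic)
#' objective: \code{dq = dq_gyro - beta * grad(f) / |grad(f)|}, integrated
#' over \code{dt} and renormalized.  One gradient iteration per sample.
#'
#' @param q_prev previous unit quaternion.
#' @param omega gyroscope sample, rad/s.
#' @param accel accelerometer sample, m/s^2; if (near) zero the correction is
#'   skipped and the step falls back to gyroscope-only propagation.
#' @param mag magnetometer sample, microtesla, or \code{NULL}.
#' @param cfg \code{\link{ahrs_config}}.
#' @return unit quaternion after the fused step.
#' @export
madgwick_update <- function(q_prev, omega, accel, mag, cfg) {
  dt <- cfg$sample_period
  qdot <- 0.5 * unclass(quat_multiply(q_prev,
                                      quat(0, omega[1], omega[2], omega[3])))
  na <- sqrt(sum(accel^2))
  if (cfg$beta > 0 && na > 1e-9) {
    a_hat <- accel / na
    f <- quat_rotate_inv(q_prev, GRAVITY_REF) - a_hat
    J <- objective_jacobian(q_prev, GRAVITY_REF)
    if (cfg$use_magnetometer && !is.null(mag) && sqrt(sum(mag^2)) > 1e-12) {
      b <- magnetic_reference(q_prev, mag)
      m_hat <- mag / sqrt(sum(mag^2))
      f <- c(f, quat_rotate_inv(q_prev, b) - m_hat)
      J <- rbind(J, objective_jacobian(q_prev, b))
    }
    grad <- drop(crossprod(J, f))
    ng <- sqrt(sum(grad^2))
    if (ng > 1e-12) qdot <- qdot - cfg$beta * grad / ng
  }
  quat_normalize(unclass(q_prev) + qdot * dt)
}

#' Initial orientation from accelerometer (and magnetometer) samples
#'
#' TRIAD-style closed-form attitude: the measured specific force fixes the
#' Earth z-axis in the sensor frame; the horizontal part of the magnetic
#' field fixes the reference horizontal axis (the same axis the fusion
#' filter's magnetic objective uses, so the filter starts at its own
#' magnetic equilibrium).  Without a magnetometer the heading is arbitrary
#' and chosen so the sensor x-axis has zero estimated-east tilt.
#'
#' Averaging a short quiet stretch of samples before calling this reduces
#' noise in the initial estimate.
#'
#' @param accel mean accelerometer sample, m/s^2 (nonzero).
#' @param mag mean magnetometer sample, microtesla, or \code{NULL}.
#' @return unit quaternion (sensor to Earth).
#' @export
ahrs_init_orientation <- function(accel, mag = NULL) {
  na <- sqrt(sum(accel^2))
  if (na < 1e-9) stop("zero accelerometer sample cannot fix the vertical")
  z_s <- accel / na                      # Earth z expressed in sensor frame
  if (!is.null(mag) && sqrt(sum(mag^2)) > 1e-12) {
    mh <- mag - sum(mag * z_s) * z_s     # horizontal field, sensor frame
    if (sqrt(sum(mh^2)) < 1e-9) stop("magnetic field parallel to gravity")
    x_s <- mh / sqrt(sum(mh^2))
  } else {
    ex <- c(1, 0, 0) - z_s[1] * z_s
    if (sqrt(sum(ex^2)) < 1e-9) ex <- c(0, 1, 0) - z_s[2] * z_s
    x_s <- ex / sqrt(sum(ex^2))
  }
  y_s <- cross3(z_s, x_s)
  quat_from_matrix(rbind(x_s, y_s, z_s))
}

#' Run the fusion filter over aligned sensor series
#'
#' @param accel n x 3 matrix of accelerometer samples (m/s^2).
#' @param gyro n x 3 matrix of gyroscope samples (rad/s).
#' @param mag n x 3 matrix of magnetometer samples (microtesla) on the same
#'   time base (sample-and-hold aligned upstream), or \code{NULL} for
#'   IMU-only fusion.
#' @param cfg \code{\link{ahrs_config}}; \code{cfg$sample_period} is the
#'   uniform spacing of the aligned series.
#' @return n x 4 matrix of unit quaternions (scalar first), one per sample;
#'   row i is the estimate after processing sample i starting from
#'   \code{cfg$initial_q}.
#' @export
run_ahrs <- function(accel, gyro, mag = NULL, cfg) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  n <- nrow(accel)
  if (nrow(gyro) != n) stop("accelerometer and gyroscope lengths differ")
  if (!is.null(mag)) {
    mag <- as.matrix(mag)
    if (nrow(mag) != n) stop("magnetometer length differs from accelerometer")
  }
  out <- matrix(NA_real_, n, 4)
  colnames(out) <- c("w", "x", "y", "z")
  q <- quat_normalize(cfg$initial_q)
  for (i in seq_len(n)) {
    q <- madgwick_update(q, gyro[i, ], accel[i, ],
                         if (is.null(mag)) NULL else mag[i, ], cfg)
    out[i, ] <- q
  }
  out
}
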