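GRAVITY_MS2 <- 9.81

#' Earth-frame linear acceleration
#'
#' Rotates sensor-frame accelerometer samples into the ENU Earth frame with
#' the per-sample orientation quaternions and subtracts the gravity vector
#' (0, 0, 9.81) m/s^2.
#'
#' @param qmat n x 4 matrix of unit quaternions (scalar first) or a single
#'   quaternion recycled over all samples.
#' @param accel n x 3 matrix of sensor-frame accelerometer samples (m/s^2).
#' @return n x 3 matrix of Earth-frame linear acceleration (m/s^2).
#' @export
earth_linear_accel <- function(qmat, accel) {
  accel <- as.matrix(accel)
  if (inherits(qmat, "quaternion") || length(qmat) == 4L)
    qmat <- matrix(as.numeric(qmat), nrow(accel), 4, byrow = TRUE)
  qmat <- as.matrix(qmat)
  if (nrow(qmat) != nrow(accel))
    stop("quaternion and accelerometer sample counts differ")
  out <- matrix(NA_real_, nrow(accel), 3)
  for (i in seq_len(nrow(accel)))
    out[i, ] <- quat_to_matrix(qmat[i, ]) %*% accel[i, ]
  out[, 3] <- out[, 3] - GRAVITY_MS2
  colnames(out) <- c("x", "y", "z")
  out
}

#' Double-integrate acceleration to position with drift filtering
#'
#' Velocity is the cumulative trapezoidal integral of acceleration and
#' position the cumulative trapezoidal integral of velocity; after each
#' integration a zero-phase high-pass Butterworth filter (default order 5,
#' cutoff 0.01 Hz) suppresses the unbounded drift that sensor bias and
#' orientation error inject.  Integration starts from zero velocity and
#' position at the first sample.
#'
#' @param accel_e n x 3 Earth-frame linear acceleration (m/s^2).
#' @param rate uniform sampling rate in Hz (> 0).
#' @param drift_filter \code{\link{filter_spec}} applied after each
#'   integration, or \code{NULL} to bypass (useful for closed-form checks).
#' @param t optional time vector (seconds) for the output.
#' @return object of class \code{"pose_series"}: list with \code{t},
#'   \code{accel}, \code{velocity}, \code{position} (n x 3 matrices, SI
#'   units, ENU frame) and optionally \code{orientation}.
#' @export
integrate_position <- function(accel_e, rate, drift_filter = drift_filter_spec(),
                               t = NULL) {
  if (rate <= 0) stop("rate must be > 0")
  accel_e <- as.matrix(accel_e)
  dt <- 1 / rate
  vel <- cumtrapz_uniform(accel_e, dt)
  if (!is.null(drift_filter)) vel <- apply_highpass(vel, drift_filter, rate)
  pos <- cumtrapz_uniform(vel, dt)
  if (!is.null(drift_filter)) pos <- apply_highpass(pos, drift_filter, rate)
  if (is.null(t)) t <- (seq_len(nrow(accel_e)) - 1L) * dt
  structure(list(t = t, accel = accel_e, velocity = vel, position = pos),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series: %d samples over %.2f s>\n",
              length(x$t), diff(range(x$t))))
  invisible(x)
}

#' Reach distance along the principal horizontal direction
#'
#' Restricts the position series to a movement window, projects onto the
#' horizontal (XOY) plane, finds the principal axis of the centred XY point
#' cloud (leading eigenvector of its 2 x 2 covariance), and reports the
#' extent of the movement as the range of the scalar projections onto that
#' axis, in centimetres.  The direction is oriented to a non-negative east
#' component; for near-isotropic clouds the axis with the larger projected
#' range wins.
#'
#' @param pose \code{\link{integrate_position}} result (positions in m).
#' @param window list or one-row data.frame with \code{start} and \code{end}
#'   in the same time base as \code{pose$t}; \code{NULL} uses the full series.
#' @return list of class \code{"reach_result"}: \code{distance_cm},
#'   \code{direction} (unit 2-vector in XY), \code{window}.
#' @export
reach_distance <- function(pose, window = NULL) {
  if (is.null(window))
    window <- list(start = min(pose$t), end = max(pose$t))
  idx <- which(pose$t >= window$start - 1e-9 & pose$t <= window$end + 1e-9)
  if (length(idx) < 2) stop("fewer than 2 samples in the movement window")
  xy <- pose$position[idx, 1:2, drop = FALSE]
  ctr <- sweep(xy, 2, colMeans(xy))
  cv <- crossprod(ctr) / nrow(ctr)
  eg <- eigen(cv, symmetric = TRUE)
  ax1 <- eg$vectors[, 1]; ax2 <- eg$vectors[, 2]
  r1 <- diff(range(ctr %*% ax1)); r2 <- diff(range(ctr %*% ax2))
  # near-isotropic tie-break: larger projected range wins
  if (abs(eg$values[1] - eg$values[2]) < 1e-12 * max(eg$values[1], 1) &&
      r2 > r1) { ax1 <- ax2; r1 <- r2 }
  if (ax1[1] < 0 || (ax1[1] == 0 && ax1[2] < 0)) ax1 <- -ax1
  structure(list(distance_cm = 100 * r1, direction = ax1,
                 window = window), class = "reach_result")
}

#' @export
print.reach_result <- function(x, ...) {
  cat(sprintf("<reach %.2f cm along (%.3f, %.3f) in [%.2f, %.2f] s>\n",
              x$distance_cm, x$direction[1], x$direction[2],
              x$window$start, x$window$end))
  invisible(x)
}
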