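STREAM_KINDS <- c("accelerometer", "gyroscope", "magnetometer", "gravity",
                  "linear_acceleration", "rotation_vector")

STREAM_UNITS <- c(accelerometer = "m/s^2", gyroscope = "rad/s",
                  magnetometer = "uT", gravity = "m/s^2",
                  linear_acceleration = "m/s^2", rotation_vector = "unitless")

#' Construct a timestamped sensor stream
#'
#' One sensor kind's triaxial time series (the rotation-vector kind carries a
#' fourth component).  Two timestamp tracks mirror typical mobile recordings:
#' a millisecond system clock and a nanosecond sensor-event clock; the
#' nanosecond track is authoritative for all time computations.
#'
#' @param kind one of accelerometer, gyroscope, magnetometer, gravity,
#'   linear_acceleration, rotation_vector.
#' @param t_ns nanosecond sensor timestamps, strictly increasing.
#' @param values n x 3 matrix (n x 4 for rotation_vector).
#' @param t_ms millisecond system timestamps (derived from \code{t_ns} when
#'   omitted).
#' @param rate uniform sampling rate in Hz if the stream is on a uniform
#'   grid, else \code{NA}.
#' @return object of class \code{"sensor_stream"}.
#' @export
sensor_stream <- function(kind, t_ns, values, t_ms = NULL, rate = NA_real_) {
  kind <- match.arg(kind, STREAM_KINDS)
  values <- as.matrix(values)
  t_ns <- as.numeric(t_ns)
  if (nrow(values) != length(t_ns))
    stop("value rows must equal timestamp count")
  bad <- which(diff(t_ns) <= 0)
  if (length(bad))
    stop(sprintf("timestamps not strictly increasing at index %d", bad[1] + 1L))
  ncomp <- if (kind == "rotation_vector") 4L else 3L
  if (ncol(values) != ncomp)
    stop(sprintf("%s stream needs %d value columns", kind, ncomp))
  if (is.null(t_ms)) t_ms <- round((t_ns - t_ns[1]) / 1e6)
  structure(list(kind = kind, t_ms = as.numeric(t_ms), t_ns = t_ns,
                 values = values, units = STREAM_UNITS[[kind]], rate = rate),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream %s: %d samples, %.2f s, units %s%s>\n",
              x$kind, nrow(x$values), diff(range(stream_time(x))), x$units,
              if (is.finite(x$rate)) sprintf(", %g Hz", x$rate) else ""))
  invisible(x)
}

#' Stream time in seconds from the first sample
#' @param stream \code{\link{sensor_stream}}.
#' @return numeric vector of per-sample times (s), starting at 0.
#' @export
stream_time <- function(stream) (stream$t_ns - stream$t_ns[1]) / 1e9

#' Resample a stream onto a uniform grid by cubic-spline interpolation
#'
#' Interpolates each axis with a cubic spline over the nanosecond time base
#' and evaluates on a grid with spacing exactly \code{1/rate}, spanning the
#' recorded interval.  Cubic splines reproduce polynomials up to degree 3
#' exactly, so smooth signals sampled with timestamp jitter are recovered to
#' interpolation accuracy.
#'
#' @param stream \code{\link{sensor_stream}} with at least 4 samples.
#' @param rate target rate in Hz.
#' @return uniform-rate \code{\link{sensor_stream}}.
#' @export
resample_uniform <- function(stream, rate = 100) {
  if (rate <= 0) stop("rate must be > 0")
  t <- stream_time(stream)
  if (length(t) < 4) stop("need at least 4 samples for cubic-spline resampling")
  n_out <- floor((t[length(t)] - t[1]) * rate + 1e-9) + 1L
  grid <- t[1] + (seq_len(n_out) - 1L) / rate
  vals <- vapply(seq_len(ncol(stream$values)), function(j) {
    f <- stats::splinefun(t, stream$values[, j], method = "fmm")
    f(grid)
  }, numeric(n_out))
  sensor_stream(stream$kind, t_ns = stream$t_ns[1] + grid * 1e9,
                values = vals, rate = rate)
}

#' Remove the gravitational (DC/very-low-frequency) component
#'
#' Applies the high-pass gravity filter (default: FIR, order 1000, 1 Hz
#' cutoff) per axis, zero phase, so the output stays aligned with the input
#' timestamps.  Requires a uniform-rate stream.
#'
#' @param stream uniform-rate \code{\link{sensor_stream}}.
#' @param spec \code{\link{filter_spec}}; default \code{gravity_filter_spec()}.
#' @return filtered \code{\link{sensor_stream}} of kind
#'   \code{linear_acceleration} (same timestamps).
#' @export
highpass_gravity <- function(stream, spec = gravity_filter_spec()) {
  if (!is.finite(stream$rate)) stop("highpass_gravity needs a uniform-rate stream (resample first)")
  vals <- apply_highpass(stream$values, spec, stream$rate)
  out_kind <- if (stream$kind == "accelerometer") "linear_acceleration" else stream$kind
  sensor_stream(out_kind, t_ns = stream$t_ns, t_ms = stream$t_ms,
                values = vals, rate = stream$rate)
}

#' Detect movement windows in an acceleration stream
#'
#' Detector: each axis is first band-limited to the voluntary-movement band
#' (zero-phase order-2 Butterworth high- and low-pass at \code{band_hz}),
#' which removes gravity/DC below the band and keeps wide-band sensor noise
#' out of the threshold statistic.  The moving-RMS envelope (window
#' \code{rms_window_s}) of the band-limited vector magnitude is thresholded
#' at \code{k} times its median; contiguous supra-threshold bursts closer
#' than \code{width_s} are merged, and a fixed-width window of
#' \code{width_s} seconds is centred on each burst's envelope centroid.
#' Windows that would extend past the recording are clipped and flagged.
#'
#' @param stream uniform-rate acceleration \code{\link{sensor_stream}} (raw
#'   or already gravity-filtered; the band-pass removes any DC either way).
#' @param rms_window_s moving-RMS window length in seconds.
#' @param k threshold multiplier on the median envelope.
#' @param width_s window width in seconds (default 5).
#' @param band_hz detector pass band \code{c(low, high)} in Hz; \code{NULL}
#'   disables band-limiting.
#' @return data.frame with columns \code{start}, \code{end}, \code{center}
#'   (seconds from stream start) and \code{clipped} (logical); zero rows on
#'   quiescent input.
#' @export
detect_movement_windows <- function(stream, rms_window_s = 1, k = 4,
                                    width_s = 5, band_hz = c(0.3, 3)) {
  if (!is.finite(stream$rate)) stop("detector needs a uniform-rate stream")
  t <- stream_time(stream)
  vals <- stream$values
  if (!is.null(band_hz)) {
    hp <- butter_sos(2, band_hz[1], stream$rate, "high")
    lp <- butter_sos(2, band_hz[2], stream$rate, "low")
    vals <- apply(vals, 2, function(col)
      sos_filtfilt(lp, sos_filtfilt(hp, col)))
  }
  mag2 <- rowSums(vals^2)
  w <- max(1L, round(rms_window_s * stream$rate))
  env <- sqrt(as.numeric(stats::filter(mag2, rep(1 / w, w), sides = 2)))
  env[is.na(env)] <- 0
  # the 5%-of-peak floor keeps the (non-causal) filter tails of strong
  # bursts from linking separate movements when the quiescent floor is tiny
  thr <- max(k * stats::median(env), 0.05 * max(env))
  if (max(env) <= thr || thr == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      center = numeric(0), clipped = logical(0)))
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bursts <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  # merge bursts whose gaps are below the window width
  merged <- bursts[1, , drop = FALSE]
  if (nrow(bursts) > 1) {
    for (b in 2:nrow(bursts)) {
      gap <- t[bursts$i0[b]] - t[merged$i1[nrow(merged)]]
      if (gap < width_s) merged$i1[nrow(merged)] <- bursts$i1[b]
      else merged <- rbind(merged, bursts[b, ])
    }
  }
  span <- range(t)
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(b) {
    idx <- merged$i0[b]:merged$i1[b]
    centroid <- sum(t[idx] * env[idx]) / sum(env[idx])
    s <- centroid - width_s / 2; e <- centroid + width_s / 2
    clip <- s < span[1] || e > span[2]
    data.frame(start = max(s, span[1]), end = min(e, span[2]),
               center = centroid, clipped = clip)
  }))
  rownames(out) <- NULL
  out
}

#' Align accelerometer, gyroscope and magnetometer onto one uniform grid
#'
#' The accelerometer and gyroscope are cubic-spline resampled at
#' \code{rate}; the (typically slower) magnetometer is aligned by
#' sample-and-hold (last observed value), never interpolated.  The common
#' grid spans the overlap of the accelerometer and gyroscope recordings.
#'
#' @param acc,gyr \code{\link{sensor_stream}}s (accelerometer, gyroscope).
#' @param mag magnetometer \code{\link{sensor_stream}} or \code{NULL}.
#' @param rate target rate in Hz (default 100).
#' @return list with \code{t} (seconds from grid start), \code{accel},
#'   \code{gyro}, \code{mag} (n x 3 matrices; \code{mag} may be NULL) and
#'   \code{rate}.
#' @export
align_streams <- function(acc, gyr, mag = NULL, rate = 100) {
  ta <- stream_time(acc); tg <- stream_time(gyr) +
    (gyr$t_ns[1] - acc$t_ns[1]) / 1e9
  t0 <- max(ta[1], tg[1]); t1 <- min(ta[length(ta)], tg[length(tg)])
  if (t1 <= t0) stop("accelerometer and gyroscope recordings do not overlap")
  n <- floor((t1 - t0) * rate + 1e-9) + 1L
  grid <- t0 + (seq_len(n) - 1L) / rate
  interp <- function(stream, offset) {
    ts <- stream_time(stream) + offset
    vapply(seq_len(ncol(stream$values)), function(j)
      stats::splinefun(ts, stream$values[, j], method = "fmm")(grid),
      numeric(n))
  }
  accel <- interp(acc, 0)
  gyro <- interp(gyr, (gyr$t_ns[1] - acc$t_ns[1]) / 1e9)
  magm <- NULL
  if (!is.null(mag)) {
    tm <- stream_time(mag) + (mag$t_ns[1] - acc$t_ns[1]) / 1e9
    magm <- vapply(seq_len(3), function(j) {
      stats::approx(tm, mag$values[, j], xout = grid, method = "constant",
                    rule = 2, f = 0)$y
    }, numeric(n))
  }
  list(t = grid - grid[1], accel = accel, gyro = gyro, mag = magm,
       rate = rate, t0_ns = acc$t_ns[1] + t0 * 1e9)
}
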