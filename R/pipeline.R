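# enforce sign continuity of a quaternion series (q and -q are the same
# rotation; componentwise interpolation needs a continuous representative)
quat_series_continuous <- function(qmat) {
  for (i in seq_len(nrow(qmat))[-1])
    if (sum(qmat[i, ] * qmat[i - 1, ]) < 0) qmat[i, ] <- -qmat[i, ]
  qmat
}

#' Simulate a synthetic assessment and write it to the CSV schema
#'
#' Runs the MARG simulator and stores the result in the ten-file assessment
#' layout, with the true per-attempt reach recorded as the "manual"
#' measurement and a \code{*_truth.csv} sidecar holding the synthetic ground
#' truth (orientation and position per sample).
#'
#' @param folder destination directory.
#' @param cfg \code{\link{synth_config}}.
#' @param subject_id,assessment_number identifiers used in file names.
#' @return invisibly, a list with the \code{\link{assessment_recording}} and
#'   the truth sidecar path.
#' @export
frt_simulate <- function(folder, cfg = synth_config(), subject_id = "synth",
                         assessment_number = 1L) {
  sim <- simulate_frt_trial(cfg)
  rec <- assessment_recording(subject_id, assessment_number,
                              date = Sys.Date(),
                              manual_frt_cm = sim$truth$reach_cm,
                              streams = sim$streams)
  write_assessment(rec, folder)
  truth_file <- file.path(folder, sprintf("%s_%d_truth.csv", subject_id,
                                          assessment_number))
  tr <- sim$truth
  utils::write.csv(
    data.frame(t_s = fmt_num(tr$t),
               qw = fmt_num(tr$orientation[, 1]),
               qx = fmt_num(tr$orientation[, 2]),
               qy = fmt_num(tr$orientation[, 3]),
               qz = fmt_num(tr$orientation[, 4]),
               px = fmt_num(tr$position[, 1]),
               py = fmt_num(tr$position[, 2]),
               pz = fmt_num(tr$position[, 3])),
    truth_file, row.names = FALSE, quote = FALSE)
  invisible(list(recording = rec, truth_file = truth_file, truth = tr))
}

#' Estimate FRT reach and fall risk from a recorded assessment
#'
#' Full measurement pipeline: align accelerometer/gyroscope/magnetometer on
#' a uniform grid (cubic-spline resampling; magnetometer sample-and-hold),
#' estimate orientation by gradient-descent MARG fusion, rotate the
#' accelerometer into the Earth frame and remove gravity, locate movement
#' windows on the gravity-filtered signal, and double-integrate within each
#' window (starting from zero velocity) to extract the reach distance along
#' the principal horizontal direction.
#'
#' @param rec \code{\link{assessment_recording}}, or a folder path (then
#'   \code{subject_id}/\code{assessment_number} select the files).
#' @param subject_id,assessment_number used when \code{rec} is a folder.
#' @param rate resampling rate, Hz.
#' @param beta fusion gain.  The estimation default (0.01) is deliberately
#'   an order of magnitude below the orientation-tracking default: the
#'   gravity correction absorbs sustained linear acceleration at a rate of
#'   about \code{2 * beta} rad/s, so a large gain cancels the very
#'   horizontal acceleration that is being integrated into the reach
#'   distance.  Gyroscope bias is handled by static calibration on the
#'   quiet segments instead of by a large gain.
#' @param use_magnetometer fuse the magnetometer when present.
#' @param drift_filter \code{\link{filter_spec}} applied after each
#'   integration.
#' @param detector_k threshold multiplier of the movement detector.
#' @return list of class \code{"frt_estimate"}: \code{trials} (data.frame
#'   with \code{attempt}, \code{estimated_cm}, \code{measured_cm} when
#'   available, \code{risk}), \code{summary} (one-row data.frame when manual
#'   measurements match the attempt count), \code{windows},
#'   \code{orientation} (n x 4), \code{t}, \code{rate}.
#' @export
frt_estimate <- function(rec, subject_id = NULL, assessment_number = 1L,
                         rate = 100, beta = 0.01, use_magnetometer = TRUE,
                         drift_filter = drift_filter_spec(),
                         detector_k = 4) {
  if (is.character(rec))
    rec <- suppressWarnings(read_assessment(rec, subject_id,
                                            assessment_number))
  st <- rec$streams
  if (is.null(st$acc) || is.null(st$gyr))
    stop("assessment needs accelerometer and gyroscope streams")
  al <- align_streams(st$acc, st$gyr, st$mag, rate = rate)
  usemag <- use_magnetometer && !is.null(al$mag)

  det_stream <- sensor_stream("accelerometer", t_ns = al$t * 1e9,
                              values = al$accel, rate = rate)
  windows <- detect_movement_windows(det_stream, k = detector_k)
  if (nrow(windows) == 0)
    stop("no movement detected in the recording")

  # static gyroscope bias calibration: true rates are zero outside the
  # movement windows, so the quiet-segment median estimates the bias
  quiet <- rep(TRUE, length(al$t))
  for (i in seq_len(nrow(windows)))
    quiet[al$t >= windows$start[i] - 1 & al$t <= windows$end[i] + 1] <- FALSE
  gyro <- al$gyro
  if (sum(quiet) >= rate) {   # at least 1 s of quiet data
    bias <- apply(gyro[quiet, , drop = FALSE], 2, stats::median)
    gyro <- sweep(gyro, 2, bias)
  }

  n0 <- min(nrow(al$accel), max(2L, round(rate / 4)))   # ~0.25 s quiet lead
  q0 <- ahrs_init_orientation(colMeans(al$accel[1:n0, , drop = FALSE]),
                              if (usemag) colMeans(al$mag[1:n0, , drop = FALSE]))
  cfg <- ahrs_config(sample_period = 1 / rate, beta = beta,
                     use_magnetometer = usemag, initial_q = q0)
  qmat <- run_ahrs(al$accel, gyro, al$mag, cfg)
  a_e <- earth_linear_accel(qmat, al$accel)

  # integrate the whole record (drift filter after each integration), then
  # extract the reach within each movement window
  pose <- integrate_position(a_e, rate, drift_filter = drift_filter, t = al$t)
  trials <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    rr <- reach_distance(pose, list(start = windows$start[i],
                                    end = windows$end[i]))
    data.frame(attempt = i, estimated_cm = rr$distance_cm,
               direction_x = rr$direction[1], direction_y = rr$direction[2])
  }))
  trials$risk <- classify_risk(trials$estimated_cm)
  summary <- NULL
  if (length(rec$manual_frt_cm) == nrow(trials)) {
    trials$measured_cm <- rec$manual_frt_cm
    summary <- summarize_assessment(
      estimated_cm = trials$estimated_cm, measured_cm = trials$measured_cm)
  }
  structure(list(trials = trials, summary = summary, windows = windows,
                 orientation = qmat, t = al$t, rate = rate,
                 earth_accel = a_e),
            class = "frt_estimate")
}

#' @export
print.frt_estimate <- function(x, ...) {
  cat("FRT assessment estimate\n")
  cat(sprintf("  %d attempt(s) detected\n", nrow(x$trials)))
  for (i in seq_len(nrow(x$trials)))
    cat(sprintf("  attempt %d: %.2f cm  [%s]%s\n", i,
                x$trials$estimated_cm[i], x$trials$risk[i],
                if ("measured_cm" %in% names(x$trials))
                  sprintf("  (manual %.2f cm)", x$trials$measured_cm[i])
                else ""))
  if (!is.null(x$summary))
    cat(sprintf("  summary: estimated %.2f cm, measured %.2f cm, error %.2f cm\n",
                x$summary$avg_estimated_cm, x$summary$avg_measured_cm,
                x$summary$avg_error_cm))
  invisible(x)
}

#' Benchmark the fusion orientation against a reference quaternion stream
#'
#' Runs the fusion pipeline on an assessment carrying a rotation-vector
#' reference stream, converts both orientation series to Tait-Bryan angles,
#' drops a warm-up interval at the start (convergence transient), applies
#' the yaw offset correction to the reference, and reports per-angle MAE,
#' MSE and RMSE.
#'
#' @param rec \code{\link{assessment_recording}} (or folder path) with a
#'   \code{rot} stream.
#' @param subject_id,assessment_number used when \code{rec} is a folder.
#' @param rate,beta,use_magnetometer fusion settings (see
#'   \code{\link{frt_estimate}}).
#' @param warmup_s seconds excluded at the start (default 1).
#' @param yaw_offset degrees subtracted from the reference yaw (default 90).
#' @return list: \code{report} (see \code{\link{benchmark_orientation}}),
#'   \code{estimate_euler}, \code{reference_euler}, \code{t}.
#' @export
frt_benchmark <- function(rec, subject_id = NULL, assessment_number = 1L,
                          rate = 100, beta = 0.1, use_magnetometer = TRUE,
                          warmup_s = 1, yaw_offset = 90) {
  if (is.character(rec))
    rec <- suppressWarnings(read_assessment(rec, subject_id,
                                            assessment_number))
  st <- rec$streams
  if (is.null(st$rot))
    stop("benchmark needs a rotation-vector reference stream ('rot')")
  al <- align_streams(st$acc, st$gyr, st$mag, rate = rate)
  usemag <- use_magnetometer && !is.null(al$mag)
  n0 <- min(nrow(al$accel), max(2L, round(rate / 4)))
  q0 <- ahrs_init_orientation(colMeans(al$accel[1:n0, , drop = FALSE]),
                              if (usemag) colMeans(al$mag[1:n0, , drop = FALSE]))
  cfg <- ahrs_config(sample_period = 1 / rate, beta = beta,
                     use_magnetometer = usemag, initial_q = q0)
  qmat <- run_ahrs(al$accel, al$gyro, al$mag, cfg)

  # reference quaternions (X,Y,Z vector part, rotL scalar) onto the fusion
  # grid: sign-continuous componentwise spline, renormalized
  tr <- stream_time(st$rot) + (st$rot$t_ns[1] - al$t0_ns) / 1e9
  qr <- quat_series_continuous(st$rot$values[, c(4, 1, 2, 3)])
  keep <- al$t >= max(tr[1], warmup_s) & al$t <= tr[length(tr)]
  grid <- al$t[keep]
  qref <- vapply(1:4, function(j)
    stats::splinefun(tr, qr[, j], method = "fmm")(grid), numeric(length(grid)))
  qref <- qref / sqrt(rowSums(qref^2))
  est_e <- quat_series_to_euler(qmat[keep, , drop = FALSE])
  ref_e <- quat_series_to_euler(qref)
  list(report = benchmark_orientation(est_e, ref_e, yaw_offset = yaw_offset),
       estimate_euler = est_e, reference_euler = ref_e, t = grid)
}

#' Summarize a table of per-trial results into per-subject averages
#'
#' Takes per-trial rows (\code{subject}, \code{estimated_cm},
#' \code{measured_cm}) and produces one row per subject with the average
#' estimated and measured reach and the absolute difference of the averages.
#'
#' @param trials data.frame or path to a CSV with the three columns above.
#' @return data.frame, one row per subject.
#' @export
frt_summarize <- function(trials) {
  if (is.character(trials)) trials <- utils::read.csv(trials)
  need <- c("subject", "estimated_cm", "measured_cm")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing column: ", miss[1])
  out <- do.call(rbind, lapply(split(trials, trials$subject), function(d)
    cbind(subject = d$subject[1], summarize_assessment(
      estimated_cm = d$estimated_cm, measured_cm = d$measured_cm))))
  rownames(out) <- NULL
  out
}
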