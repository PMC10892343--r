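#' Error metrics between two paired series
#'
#' Mean absolute error, mean squared error and root mean squared error of
#' predictions \code{y} against truth \code{x}.
#'
#' @param y predictions.
#' @param x reference values of the same length.
#' @return named vector \code{c(mae, mse, rmse)}.
#' @export
#' @examples
#' error_metrics(c(1, 2, 3), c(0, 0, 0))  # mae 2, mse 14/3
error_metrics <- function(y, x) {
  if (length(y) == 0) stop("empty input")
  if (length(y) != length(x)) stop("length mismatch")
  d <- y - x
  mse <- mean(d^2)
  c(mae = mean(abs(d)), mse = mse, rmse = sqrt(mse))
}

#' Fall-risk class from a reach distance
#'
#' Reach above 25.40 cm is a negative test (low fall risk); 15.24-25.40 cm
#' (inclusive) indicates a doubled risk of falling within six months; below
#' 15.24 cm a quadrupled risk.
#'
#' @param reach_cm reach distance in centimetres (>= 0); vectorized.
#' @return character vector with levels \code{low_risk}, \code{double_risk},
#'   \code{quadruple_risk}.
#' @export
#' @examples
#' classify_risk(c(30, 20, 10))
classify_risk <- function(reach_cm) {
  if (any(reach_cm < 0)) stop("reach distance cannot be negative")
  ifelse(reach_cm > 25.40, "low_risk",
         ifelse(reach_cm >= 15.24, "double_risk", "quadruple_risk"))
}

.FRT_NORMS <- data.frame(
  age_lo = c(20, 41, 70),
  age_hi = c(40, 69, 87),
  male   = c(42.49, 38.25, 33.43),
  female = c(37.19, 35.08, 26.59)
)

#' Reference (norm) reach value by age and sex
#'
#' Band lookup over the published normative ranges for ages 20-40, 41-69 and
#' 70-87 years.  Ages outside 20-87 are an error (no extrapolation).
#'
#' @param age_years age in whole years, 20-87.
#' @param sex \code{"male"} or \code{"female"}.
#' @return norm reach in centimetres.
#' @export
#' @examples
#' frt_norm(30, "male")    # 42.49
#' frt_norm(75, "female")  # 26.59
frt_norm <- function(age_years, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (age_years < 20 || age_years > 87)
    stop("norm values cover ages 20-87 only")
  band <- which(age_years >= .FRT_NORMS$age_lo & age_years <= .FRT_NORMS$age_hi)
  if (length(band) != 1) stop("age falls between norm bands; use whole years")
  .FRT_NORMS[[sex]][band]
}

#' Summarize an assessment from per-trial estimates
#'
#' Averages the estimated and manually measured reach over the trials of one
#' assessment; the reported error is the absolute difference of the two
#' averages (not the average of per-trial errors).
#'
#' @param trials data.frame with columns \code{estimated_cm} and
#'   \code{measured_cm} (one row per trial), or two numeric vectors via
#'   \code{estimated_cm}/\code{measured_cm}.
#' @param estimated_cm,measured_cm alternative vector interface.
#' @return one-row data.frame: \code{avg_estimated_cm},
#'   \code{avg_measured_cm}, \code{avg_error_cm}, rounded to 2 decimals.
#' @export
#' @examples
#' summarize_assessment(data.frame(estimated_cm = c(17.02, 27.09),
#'                                 measured_cm = c(14.00, 25.50)))
summarize_assessment <- function(trials = NULL, estimated_cm = NULL,
                                 measured_cm = NULL) {
  if (!is.null(trials)) {
    estimated_cm <- trials$estimated_cm
    measured_cm <- trials$measured_cm
  }
  if (length(estimated_cm) == 0) stop("at least one trial required")
  if (length(estimated_cm) != length(measured_cm))
    stop("estimated and measured trial counts differ")
  est <- mean(estimated_cm); meas <- mean(measured_cm)
  data.frame(avg_estimated_cm = round2(est),
             avg_measured_cm = round2(meas),
             avg_error_cm = round2(abs(est - meas)))
}

# round half away from zero at 2 decimals (reporting convention for tables);
# the epsilon restores decimal half-up behaviour for values like 2.305 whose
# binary representation sits just below the .005 midpoint
round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100

#' Orientation benchmark report against a reference Euler-angle series
#'
#' Compares estimated roll/pitch/yaw against a reference stream.  The
#' reference yaw is first shifted by \code{yaw_offset} (degrees) to remove a
#' known constant heading offset between the two conventions, and all
#' differences are wrapped into (-180, 180] before computing MAE, MSE and
#' RMSE per angle, so errors at the +/-180 seam are not inflated.
#'
#' @param estimate n x 3 matrix (columns roll, pitch, yaw, degrees).
#' @param reference n x 3 matrix, same layout.
#' @param yaw_offset degrees subtracted from the reference yaw (default 90,
#'   the offset between a magnetic-east-referenced estimator and a
#'   north-referenced rotation vector).
#' @return data.frame with rows roll, pitch, yaw and columns mae, mse, rmse
#'   (degrees; squared degrees for mse).
#' @export
benchmark_orientation <- function(estimate, reference, yaw_offset = 90) {
  estimate <- as.matrix(estimate); reference <- as.matrix(reference)
  if (!all(dim(estimate) == dim(reference)))
    stop("estimate and reference dimensions differ")
  reference[, 3] <- wrap_angle(reference[, 3] - yaw_offset)
  out <- t(vapply(1:3, function(j) {
    d <- wrap_angle(estimate[, j] - reference[, j])
    error_metrics(d, numeric(length(d)))
  }, c(mae = 0, mse = 0, rmse = 0)))
  out <- as.data.frame(out)
  rownames(out) <- c("roll", "pitch", "yaw")
  out
}
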