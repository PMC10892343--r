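# file-suffix -> stream-kind map of the ten-file assessment schema
SUFFIX_KIND <- c(acc = "accelerometer", acc_r = "accelerometer",
                 gra = "gravity", gyr = "gyroscope", gyr_r = "gyroscope",
                 lin = "linear_acceleration", mag = "magnetometer",
                 mag_r = "magnetometer", rot = "rotation_vector")

#' Construct an assessment recording
#'
#' Bundle of one subject assessment: sensor streams keyed by file suffix
#' (acc, acc_r, gra, gyr, gyr_r, lin, mag, mag_r, rot) plus the assessment
#' date and the manually measured FRT results (one per trial).
#'
#' @param subject_id subject identifier (used in file names).
#' @param assessment_number integer assessment counter.
#' @param date assessment date (\code{Date} or ISO string).
#' @param manual_frt_cm numeric vector of manual reach measurements, cm.
#' @param streams named list of \code{\link{sensor_stream}}s keyed by suffix.
#' @return object of class \code{"assessment_recording"}.
#' @export
assessment_recording <- function(subject_id, assessment_number = 1L,
                                 date = Sys.Date(), manual_frt_cm = numeric(0),
                                 streams = list()) {
  unknown <- setdiff(names(streams), names(SUFFIX_KIND))
  if (length(unknown))
    stop("unknown stream suffix: ", paste(unknown, collapse = ", "))
  for (sfx in names(streams)) {
    if (streams[[sfx]]$kind != SUFFIX_KIND[[sfx]])
      stop(sprintf("stream '%s' must have kind '%s'", sfx, SUFFIX_KIND[[sfx]]))
  }
  structure(list(subject_id = as.character(subject_id),
                 assessment_number = as.integer(assessment_number),
                 date = as.character(date),
                 manual_frt_cm = as.numeric(manual_frt_cm),
                 streams = streams),
            class = "assessment_recording")
}

#' @export
print.assessment_recording <- function(x, ...) {
  cat(sprintf("<assessment %s #%d (%s): streams [%s], %d manual trial(s)>\n",
              x$subject_id, x$assessment_number, x$date,
              paste(names(x$streams), collapse = ", "),
              length(x$manual_frt_cm)))
  invisible(x)
}

axis_cols <- function(kind) {
  if (kind == "rotation_vector") c("X", "Y", "Z", "rotL") else c("X", "Y", "Z")
}

#' Read a ten-file CSV assessment
#'
#' Files are named \code{id_assessmentNumber[_suffix].csv}.  The suffix-less
#' metadata file holds key-value rows (date, manual FRT results as a
#' semicolon-separated string).  Sensor files carry a header row and columns
#' \code{system_ts_ms}, \code{sensor_ts_ns}, then axis columns X, Y, Z (the
#' rotation-vector file adds \code{rotL}, read as the scalar quaternion
#' component; the on-device storage convention is not standardised, so this
#' assumption is made explicit here).  Missing sensor files yield absent
#' streams with a warning.
#'
#' @param folder directory containing the files.
#' @param subject_id subject identifier.
#' @param assessment_number integer.
#' @return \code{\link{assessment_recording}}.
#' @export
read_assessment <- function(folder, subject_id, assessment_number = 1L) {
  base <- file.path(folder, sprintf("%s_%d", subject_id, assessment_number))
  meta_file <- paste0(base, ".csv")
  expected <- c(meta_file, paste0(base, "_", names(SUFFIX_KIND), ".csv"))
  if (!any(file.exists(expected)))
    stop("no assessment files found; expected e.g.: ",
         paste(basename(utils::head(expected, 3)), collapse = ", "))
  date <- NA_character_; manual <- numeric(0)
  if (file.exists(meta_file)) {
    kv <- utils::read.csv(meta_file, header = TRUE, colClasses = "character")
    if (!all(c("key", "value") %in% names(kv)))
      stop(sprintf("malformed header in %s: need columns 'key','value'",
                   basename(meta_file)))
    get <- function(k) kv$value[match(k, kv$key)]
    if (!is.na(get("date"))) date <- get("date")
    if (!is.na(get("manual_frt_cm")) && nzchar(get("manual_frt_cm")))
      manual <- as.numeric(strsplit(get("manual_frt_cm"), ";")[[1]])
  } else warning("metadata file missing: ", basename(meta_file))
  streams <- list()
  for (sfx in names(SUFFIX_KIND)) {
    f <- paste0(base, "_", sfx, ".csv")
    if (!file.exists(f)) next
    kind <- SUFFIX_KIND[[sfx]]
    df <- utils::read.csv(f, header = TRUE)
    need <- c("system_ts_ms", "sensor_ts_ns", axis_cols(kind))
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop(sprintf("malformed header in %s: missing column '%s'",
                   basename(f), miss[1]))
    vals <- suppressWarnings(
      matrix(as.numeric(as.matrix(df[, axis_cols(kind)])), nrow(df)))
    if (anyNA(vals)) {
      bad <- which(apply(is.na(vals), 1, any))[1]
      stop(sprintf("non-numeric cell in %s at data row %d", basename(f), bad))
    }
    streams[[sfx]] <- sensor_stream(kind, t_ns = df$sensor_ts_ns,
                                    values = vals, t_ms = df$system_ts_ms)
  }
  absent <- setdiff(names(SUFFIX_KIND), names(streams))
  if (length(absent))
    warning("absent streams: ", paste(absent, collapse = ", "))
  assessment_recording(subject_id, assessment_number, date = date,
                       manual_frt_cm = manual, streams = streams)
}

#' Write an assessment to the ten-file CSV schema
#'
#' Inverse of \code{\link{read_assessment}}: values round-trip through
#' decimal-point, comma-delimited UTF-8 CSV at full double precision.
#' Streams absent from the recording are simply not written.
#'
#' @param rec \code{\link{assessment_recording}}.
#' @param folder destination directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_assessment <- function(rec, folder) {
  if (!dir.exists(folder) && !dir.create(folder, recursive = TRUE))
    stop("cannot create destination folder: ", folder)
  base <- file.path(folder, sprintf("%s_%d", rec$subject_id,
                                    rec$assessment_number))
  files <- paste0(base, ".csv")
  meta <- data.frame(key = c("subject_id", "assessment_number", "date",
                             "manual_frt_cm"),
                     value = c(rec$subject_id,
                               as.character(rec$assessment_number),
                               rec$date,
                               paste(fmt_num(rec$manual_frt_cm),
                                     collapse = ";")))
  utils::write.csv(meta, files[1], row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  for (sfx in names(rec$streams)) {
    s <- rec$streams[[sfx]]
    df <- data.frame(system_ts_ms = fmt_num(s$t_ms),
                     sensor_ts_ns = sprintf("%.0f", s$t_ns))
    vals <- s$values
    for (j in seq_len(ncol(vals)))
      df[[axis_cols(s$kind)[j]]] <- fmt_num(vals[, j])
    f <- paste0(base, "_", sfx, ".csv")
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    files <- c(files, f)
  }
  invisible(files)
}

fmt_num <- function(x) sprintf("%.12g", x)
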