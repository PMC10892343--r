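#' Specify a high-pass filter
#'
#' @param family \code{"FIR"} (windowed-sinc, used for gravity removal) or
#'   \code{"Butterworth"} (IIR, used for integration drift removal).
#' @param order filter order (> 0).
#' @param cutoff_hz cutoff frequency in Hz; must be below the Nyquist
#'   frequency of the stream it is applied to.
#' @return object of class \code{"filter_spec"}.
#' @export
filter_spec <- function(family = c("FIR", "Butterworth"), order, cutoff_hz) {
  family <- match.arg(family)
  if (order <= 0) stop("filter order must be > 0")
  if (cutoff_hz <= 0) stop("cutoff must be > 0")
  structure(list(family = family, response = "high",
                 order = as.integer(order), cutoff_hz = cutoff_hz),
            class = "filter_spec")
}

#' Default gravity-removal filter: high-pass FIR, order 1000, 1 Hz cutoff
#' @return \code{\link{filter_spec}}.
#' @export
gravity_filter_spec <- function() filter_spec("FIR", 1000L, 1)

#' Default drift-removal filter: high-pass Butterworth, order 5, 0.01 Hz
#' @return \code{\link{filter_spec}}.
#' @export
drift_filter_spec <- function() filter_spec("Butterworth", 5L, 0.01)

# ---- Butterworth high-pass as second-order sections -------------------------
#
# At cutoff/Nyquist ratios as small as 2e-4 the expanded transfer-function
# polynomial is ill-conditioned (all poles clustered at z = 1), so the filter
# is designed and applied as a cascade of bilinear-transformed biquads built
# directly from the analog Butterworth prototype poles.

butter_sos <- function(order, cutoff_hz, fs, type = c("high", "low")) {
  type <- match.arg(type)
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order) + pi / 2
  p_lp <- complex(modulus = 1, argument = theta)
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)       # prewarped analog cutoff
  p <- if (type == "high") wc / p_lp else wc * p_lp
  sections <- list()
  used <- rep(FALSE, order)
  K <- 2 * fs                                   # bilinear s = K (z-1)/(z+1)
  for (i in seq_len(order)) {
    if (used[i]) next
    pi1 <- p[i]
    if (abs(Im(pi1)) < 1e-12) {
      used[i] <- TRUE
      r <- Re(pi1)
      zp <- (K + r) / (K - r)
      if (type == "high")   # H(s) = s / (s - p)
        sections[[length(sections) + 1]] <-
          list(b = K / (K - r) * c(1, -1, 0), a = c(1, -zp, 0))
      else                  # H(s) = -p / (s - p)
        sections[[length(sections) + 1]] <-
          list(b = -r / (K - r) * c(1, 1, 0), a = c(1, -zp, 0))
    } else {
      j <- which(!used & abs(p - Conj(pi1)) < 1e-8 * abs(pi1))[1]
      used[c(i, j)] <- TRUE
      # denominator s^2 - 2 Re(p) s + |p|^2 under the bilinear transform
      a0 <- K^2 - 2 * Re(pi1) * K + abs(pi1)^2
      a1 <- 2 * (abs(pi1)^2 - K^2)
      a2 <- K^2 + 2 * Re(pi1) * K + abs(pi1)^2
      bq <- if (type == "high") K^2 / a0 * c(1, -2, 1)   # numerator s^2
            else abs(pi1)^2 / a0 * c(1, 2, 1)            # numerator |p|^2
      sections[[length(sections) + 1]] <-
        list(b = bq, a = c(1, a1 / a0, a2 / a0))
    }
  }
  sections
}

butter_highpass_sos <- function(order, cutoff_hz, fs)
  butter_sos(order, cutoff_hz, fs, "high")

# direct-form-II-transposed biquad; a = c(1, a1, a2).  The state is
# initialized to its steady-state response to a constant input x[1], so a
# DC-offset input produces no startup transient.
biquad_filter <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  g <- sum(b) / (1 + a[2] + a[3])        # DC gain
  y0 <- g * x[1]
  s2 <- b[3] * x[1] - a[3] * y0
  s1 <- b[2] * x[1] - a[2] * y0 + s2
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + s1
    s1 <- b[2] * x[i] - a[2] * y[i] + s2
    s2 <- b[3] * x[i] - a[3] * y[i]
  }
  y
}

# zero-phase (forward-backward) filtering with odd-reflection padding,
# applied section by section
sos_filtfilt <- function(sections, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 3L * 10L * length(sections))
  pre  <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  xe <- c(pre, x, post)
  for (s in sections) {
    xe <- biquad_filter(s$b, s$a, xe)
    xe <- rev(biquad_filter(s$b, s$a, rev(xe)))
  }
  xe[seq(padlen + 1, padlen + n)]
}

# zero-phase FIR filtering with odd-reflection padding
fir_filtfilt <- function(b, x) {
  n <- length(x)
  padlen <- min(n - 1L, length(b))
  pre  <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  xe <- c(pre, x, post)
  y <- signal::fftfilt(b, c(xe, numeric(length(b))))
  gd <- (length(b) - 1) / 2               # linear-phase group delay
  y <- y[seq_along(xe) + gd]              # forward pass, delay compensated
  y <- rev(y)
  y2 <- signal::fftfilt(b, c(y, numeric(length(b))))
  y2 <- rev(y2[seq_along(xe) + gd])
  y2[seq(padlen + 1, padlen + n)]
}

#' Apply a high-pass filter spec to a numeric matrix, zero phase
#'
#' Columns are filtered independently with forward-backward application, so
#' the output is delay-free and aligned with the input samples.
#'
#' @param x numeric vector or matrix (samples in rows).
#' @param spec \code{\link{filter_spec}}.
#' @param fs sampling rate in Hz.
#' @return filtered object of the same shape.
#' @export
apply_highpass <- function(x, spec, fs) {
  if (spec$cutoff_hz >= fs / 2) stop("cutoff at or above Nyquist")
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  if (spec$family == "FIR") {
    if (nrow(xm) <= spec$order)
      stop(sprintf("stream length %d not greater than FIR order %d",
                   nrow(xm), spec$order))
    b <- as.numeric(signal::fir1(spec$order, spec$cutoff_hz / (fs / 2),
                                 type = "high"))
    out <- apply(xm, 2, function(col) fir_filtfilt(b, col))
  } else {
    sections <- butter_highpass_sos(spec$order, spec$cutoff_hz, fs)
    out <- apply(xm, 2, function(col) sos_filtfilt(sections, col))
  }
  if (vec) drop(out) else out
}

# cumulative trapezoidal integral on a uniform grid
cumtrapz_uniform <- function(x, dt) {
  xm <- as.matrix(x)
  out <- apply(xm, 2, function(col) {
    c(0, cumsum((col[-1] + col[-length(col)]) / 2 * dt))
  })
  if (is.null(dim(x))) drop(out) else out
}
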