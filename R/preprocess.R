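#' Zero-phase Butterworth low-pass filter
#'
#' Applies a low-order Butterworth low-pass filter forward and then backward
#' (zero-phase), so filtered landmarks are not delayed relative to the raw
#' timeline. Edge transients are suppressed by odd-symmetric reflection
#' padding of roughly one filter settling length at each end. The default
#' (order 2, 10 Hz cut-off) is the setting used to prepare the signal for
#' Q/S/T delineation.
#'
#' Because the filter runs once in each direction, the effective magnitude
#' response is the squared single-pass response: -6 dB at the cut-off for the
#' default second-order design.
#'
#' @param x an [ecg_record()] or numeric vector.
#' @param fs sampling rate in Hz (ignored when `x` is an `ecg_record`).
#' @param order filter order (>= 1).
#' @param cutoff_hz cut-off frequency in Hz; must be below `fs / 2`.
#' @return Numeric vector of the same length as the input.
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 50 * seq(0, 1, by = 1 / fs))
#' y <- lowpass_filter(x, fs)      # 50 Hz is strongly attenuated
#' max(abs(y[200:800])) < 0.05
#' @export
lowpass_filter <- function(x, fs = NULL, order = 2, cutoff_hz = 10) {
  if (inherits(x, "ecg_record")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("'fs' is required for numeric input")
  if (order < 1) stop("'order' must be >= 1")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("'cutoff_hz' must lie in (0, fs/2)")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # pad of ~8 time constants lets the slowest pole's transient decay below
  # 1e-9, which makes forward-backward filtering commute with time reversal
  # to that accuracy
  filtfilt_reflect(bf, x, pad = ceiling(8 * fs / cutoff_hz))
}

# Forward-backward filtering with odd-symmetric reflection padding.
filtfilt_reflect <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- if (pad > 0L) {
    c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  } else {
    x
  }
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(pad + 1L):(pad + n)]
}

#' First-difference derivative
#'
#' Returns the scaled first difference `(x[i + 1] - x[i]) * fs` in mV/s.
#' Element `i` of the output refers to the interval between samples `i` and
#' `i + 1`; the output is one sample shorter than the input.
#'
#' @param x an [ecg_record()] or numeric vector (typically the low-pass
#'   filtered signal).
#' @param fs sampling rate in Hz (ignored when `x` is an `ecg_record`).
#' @return Numeric vector of length `length(x) - 1`.
#' @export
ecg_derivative <- function(x, fs = NULL) {
  if (inherits(x, "ecg_record")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("'fs' is required for numeric input")
  if (length(x) < 2L) stop("need at least 2 samples")
  diff(x) * fs
}

#' Pan-Tompkins R-peak detection
#'
#' Locates R peaks with the classic slope/amplitude/width logic: band-pass
#' filtering (default 5--15 Hz), a five-point derivative, squaring, a 150 ms
#' moving-window integration, dual adaptive thresholds with search-back, a
#' 200 ms refractory period and T-wave discrimination via the 360 ms slope
#' test. All thresholds adapt multiplicatively to the running signal and
#' noise peak estimates, so detections are invariant to scaling the record by
#' any positive constant. Each detection is finally snapped to the raw-signal
#' maximum within +/-25 ms, so the returned indices refer to the raw
#' timeline.
#'
#' @param record an [ecg_record()]; must be at least 2 s long so thresholds
#'   can be initialized.
#' @param band band-pass edges in Hz, length 2.
#' @param integration_s moving-window integration length in seconds.
#' @param refractory_s minimum spacing between detections in seconds.
#' @param twave_s window after a detection in which a low-slope candidate is
#'   discarded as a T wave.
#' @param snap_s half-width of the raw-maximum snap window in seconds.
#' @return Integer vector of strictly increasing R sample indices (empty when
#'   nothing crosses threshold).
#' @references Pan J., Tompkins W.J. (1985) A real-time QRS detection
#'   algorithm. IEEE Transactions on Biomedical Engineering 32(3):230-236.
#' @export
detect_r_peaks <- function(record, band = c(5, 15), integration_s = 0.150,
                           refractory_s = 0.200, twave_s = 0.360,
                           snap_s = 0.025) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  x <- record$samples
  n <- length(x)
  if (n < 2 * fs) stop("record must be at least 2 s long")

  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xf <- filtfilt_reflect(bf, x, pad = ceiling(3 * fs / band[1L]))

  # centered five-point derivative (zero phase, so peaks stay aligned)
  der <- c(0, 0, (-xf[1:(n - 4)] - 2 * xf[2:(n - 3)] +
                    2 * xf[4:(n - 1)] + xf[5:n]) / 8, 0, 0) * fs
  sq <- der^2
  wl <- max(1L, round(integration_s * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / wl, wl), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate peaks: local maxima of the integrated signal, pruned so only
  # the dominant maximum within any refractory window survives (the Q/S
  # slope energy produces side lobes that must not shadow the QRS peak)
  refr <- round(refractory_s * fs)
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (length(cand) == 0L) return(integer(0))
  keep <- logical(length(cand))
  for (j in order(mwi[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[j]) < refr)) keep[j] <- TRUE
  }
  cand <- cand[keep]

  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  tw <- round(twave_s * fs)
  slope_at <- function(i) {
    lo <- max(1L, i - round(0.075 * fs)); hi <- min(n, i + round(0.075 * fs))
    max(abs(der[lo:hi]))
  }

  peaks <- integer(0)
  slopes <- numeric(0)
  rr_avg <- NA_real_
  threshold <- function() npki + 0.25 * (spki - npki)
  for (i in cand) {
    if (length(peaks) && i - peaks[length(peaks)] < refr) next
    pk <- mwi[i]
    accepted <- FALSE
    if (pk > threshold()) {
      # T-wave discrimination: within 360 ms of the previous beat a
      # candidate with less than half its slope is a repolarization wave
      if (length(peaks) && i - peaks[length(peaks)] < tw &&
          slope_at(i) < 0.5 * slopes[length(slopes)]) {
        npki <- 0.125 * pk + 0.875 * npki
      } else {
        accepted <- TRUE
        spki <- 0.125 * pk + 0.875 * spki
      }
    } else {
      npki <- 0.125 * pk + 0.875 * npki
    }
    if (!accepted && length(peaks) && !is.na(rr_avg) &&
        i - peaks[length(peaks)] > 1.66 * rr_avg &&
        pk > 0.5 * threshold()) {
      accepted <- TRUE            # search-back with the lower threshold
      spki <- 0.25 * pk + 0.75 * spki
    }
    if (accepted) {
      peaks <- c(peaks, i)
      slopes <- c(slopes, slope_at(i))
      if (length(peaks) >= 2L) {
        rr <- diff(tail(peaks, 9L))
        rr_avg <- mean(rr)
      }
    }
  }
  if (length(peaks) == 0L) return(integer(0))

  # snap to the raw maximum so indices refer to the raw timeline
  sw <- round(snap_s * fs)
  snapped <- vapply(peaks, function(i) {
    lo <- max(1L, i - sw); hi <- min(n, i + sw)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  snapped <- sort(unique(snapped))
  # re-enforce the refractory spacing after snapping
  keep <- rep(TRUE, length(snapped))
  last <- snapped[1L]
  for (k in seq_along(snapped)[-1L]) {
    if (snapped[k] - last < refr) keep[k] <- FALSE else last <- snapped[k]
  }
  snapped[keep]
}
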