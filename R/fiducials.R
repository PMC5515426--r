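# Sign-change ("zero crossing") positions of a first-difference derivative.
# A crossing is reported at the later sample m, i.e. between derivative
# elements d[m - 1] and d[m]; for a local extremum of the signal this is the
# extremum sample itself. direction: "any" (sign change), "np"
# (negative -> non-negative, a local minimum), "pn" (positive ->
# non-positive, a local maximum).
deriv_crossings <- function(deriv, lo, hi, direction = c("any", "np", "pn")) {
  direction <- match.arg(direction)
  lo <- max(2L, lo)
  hi <- min(length(deriv), hi)
  if (lo > hi) return(integer(0))
  m <- lo:hi
  a <- deriv[m - 1L]
  b <- deriv[m]
  keep <- switch(direction,
    any = sign(a) != sign(b),
    np  = a < 0 & b >= 0,
    pn  = a > 0 & b <= 0)
  m[keep]
}

#' Locate the Q, S and T points of one beat
#'
#' Q, S and T are found from sign changes of the first-difference derivative
#' of the low-pass filtered signal, inside physiological windows anchored at
#' the R peak:
#'
#' * **Q**: the *last* derivative sign change in the 0.100 s window before R
#'   (the closest one to R), excluding R itself.
#' * **S**: the *first* negative-to-positive derivative transition in the
#'   0.050 s window after R.
#' * **T**: the *last* positive-to-negative transition between 0.050 s and
#'   0.400 s after R.
#'
#' Each returns `NA` ("missing") when no qualifying transition exists or the
#' window leaves the record. The S window must fit inside the record; the T
#' window is truncated at the record end.
#'
#' @param deriv first-difference derivative of the filtered signal (element
#'   `i` spans samples `i` to `i + 1`; see [ecg_derivative()] -- only signs
#'   are used, so scaling by `fs` is irrelevant).
#' @param r R-peak sample index on the same timeline.
#' @param fs sampling rate in Hz.
#' @return Sample index of the fiducial point, or `NA_integer_`.
#' @export
locate_q <- function(deriv, r, fs) {
  w <- round(0.100 * fs)
  if (r - w < 1L) return(NA_integer_)
  cr <- deriv_crossings(deriv, r - w, r - 1L, "any")
  if (length(cr)) max(cr) else NA_integer_
}

#' @rdname locate_q
#' @export
locate_s <- function(deriv, r, fs) {
  w <- round(0.050 * fs)
  if (r + w > length(deriv) + 1L) return(NA_integer_)
  cr <- deriv_crossings(deriv, r + 1L, r + w, "np")
  if (length(cr)) min(cr) else NA_integer_
}

#' @rdname locate_q
#' @export
locate_t <- function(deriv, r, fs) {
  lo <- r + round(0.050 * fs)
  hi <- r + round(0.400 * fs)
  if (lo > length(deriv)) return(NA_integer_)
  cr <- deriv_crossings(deriv, lo, hi, "pn")
  if (length(cr)) max(cr) else NA_integer_
}

#' Delineate all beats of a record
#'
#' Runs the fiducial pipeline: zero-phase low-pass filtering
#' ([lowpass_filter()]), Pan-Tompkins R detection ([detect_r_peaks()]) and
#' derivative-rule location of Q, S and T ([locate_q()], [locate_s()],
#' [locate_t()]). Each Pan-Tompkins detection is re-anchored to the local
#' maximum of the *filtered* signal within `anchor_s` before the Q/S/T
#' windows are applied, so the trivial derivative sign change at the R
#' extremum coincides with the excluded window endpoint; all reported indices
#' and intervals therefore live on one consistent (filtered-peak) timeline.
#'
#' Beats with any missing fiducial point, or whose search windows are
#' truncated by the record edges, are flagged invalid.
#'
#' @param record an [ecg_record()].
#' @param cutoff_hz,order low-pass filter settings (see [lowpass_filter()]).
#' @param anchor_s half-width (s) of the filtered-maximum re-anchoring
#'   window.
#' @param ... further arguments passed to [detect_r_peaks()].
#' @return A data frame with one row per detected beat: `beat`, `q`, `r`,
#'   `s`, `t` (sample indices, `NA` when missing) and `valid`. The sampling
#'   rate is attached as attribute `"fs"`.
#' @examples
#' tpl <- subject_template()
#' rec <- generate_record(tpl, duration_s = 10, fs = 500, seed = 1)
#' fid <- delineate(rec$record)
#' head(fid)
#' @export
delineate <- function(record, cutoff_hz = 10, order = 2, anchor_s = 0.010,
                      ...) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  r_raw <- detect_r_peaks(record, ...)
  empty <- data.frame(beat = integer(0), q = integer(0), r = integer(0),
                      s = integer(0), t = integer(0), valid = logical(0))
  attr(empty, "fs") <- fs
  if (length(r_raw) == 0L) return(empty)
  filt <- lowpass_filter(record, order = order, cutoff_hz = cutoff_hz)
  d <- diff(filt)
  n <- length(record$samples)
  aw <- round(anchor_s * fs)
  rows <- lapply(seq_along(r_raw), function(k) {
    lo <- max(1L, r_raw[k] - aw)
    hi <- min(n, r_raw[k] + aw)
    r <- lo + which.max(filt[lo:hi]) - 1L
    q <- locate_q(d, r, fs)
    s <- locate_s(d, r, fs)
    tp <- locate_t(d, r, fs)
    t_window_ok <- r + round(0.400 * fs) <= n
    valid <- !is.na(q) && !is.na(s) && !is.na(tp) && t_window_ok &&
      q < r && r < s && s < tp
    data.frame(beat = k, q = q, r = r, s = s, t = tp, valid = valid)
  })
  out <- do.call(rbind, rows)
  attr(out, "fs") <- fs
  out
}
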