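#' Per-beat interval features
#'
#' Converts delineated fiducial indices to interval features in seconds:
#' `qt = (t - q) / fs`, `rt = (t - r) / fs`, `st = (t - s) / fs`,
#' `qr = (r - q) / fs` and the preceding R-to-R interval
#' `rr = (r_i - r_(i-1)) / fs`. Only valid beats are used; the first retained
#' beat of a record has no preceding R and is dropped. The identity
#' `qt = qr + rt` holds exactly because all intervals are differences of the
#' same integer sample indices.
#'
#' @param fiducials a data frame from [delineate()] (columns `q`, `r`, `s`,
#'   `t`, `valid`), or any data frame of fiducial indices ordered by `r`.
#' @param fs sampling rate in Hz; defaults to the `"fs"` attribute of
#'   `fiducials`.
#' @param subject_id subject label stored with each row.
#' @return A data frame with columns `subject_id`, `beat_index`, `qt`, `rt`,
#'   `st`, `qr`, `rr` (all seconds) and `r_index` (the beat's R sample
#'   index, kept so that downstream code can assign beats to record blocks).
#' @export
compute_intervals <- function(fiducials, fs = attr(fiducials, "fs"),
                              subject_id = "record") {
  stopifnot(is.data.frame(fiducials))
  if (is.null(fs) || !is.numeric(fs) || fs <= 0) stop("'fs' must be > 0")
  f <- fiducials
  if (!is.null(f$valid)) f <- f[f$valid, , drop = FALSE]
  if (nrow(f) == 0L) {
    return(data.frame(subject_id = character(0), beat_index = integer(0),
                      qt = numeric(0), rt = numeric(0), st = numeric(0),
                      qr = numeric(0), rr = numeric(0), r_index = integer(0)))
  }
  if (is.unsorted(f$r, strictly = TRUE)) stop("beats must be ordered by 'r'")
  rr <- c(NA_real_, diff(f$r)) / fs
  out <- data.frame(
    subject_id = rep(as.character(subject_id), nrow(f)),
    beat_index = if (!is.null(f$beat)) f$beat else seq_len(nrow(f)),
    qt = (f$t - f$q) / fs,
    rt = (f$t - f$r) / fs,
    st = (f$t - f$s) / fs,
    qr = (f$r - f$q) / fs,
    rr = rr,
    r_index = f$r
  )
  out <- out[!is.na(out$rr), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Physiological plausibility filter for beats
#'
#' A beat is accepted when all of the following hold, tested in order (the
#' first failed rule is recorded as the rejection reason):
#'
#' 1. `qr <= qr_max` (default 0.075 s): the Q-to-R distance of a plausible
#'    QRS onset;
#' 2. `qt_rr_min < qt / rr < qt_rr_max` (defaults 0.200 and 0.360, strict
#'    bounds): the heart-rate-relative QT ratio of a plausible beat;
#' 3. optionally `rr_min <= rr <= rr_max` (defaults 0.3 s and 2.0 s): the
#'    physiological range of interbeat intervals.
#'
#' The filter is a pure per-beat predicate: it is idempotent and the accepted
#' and rejected sets partition the input.
#'
#' @param features a data frame from [compute_intervals()].
#' @param qr_max inclusive upper bound on `qr` (s).
#' @param qt_rr_min,qt_rr_max strict bounds on the dimensionless `qt / rr`.
#' @param rr_gate apply the RR range gate?
#' @param rr_min,rr_max inclusive RR bounds (s) when `rr_gate` is `TRUE`.
#' @return A list with data frames `accepted` and `rejected`; `rejected`
#'   carries a `reject_reason` column (`"qr"`, `"qt_rr"` or `"rr"`).
#' @examples
#' f <- data.frame(subject_id = "a", beat_index = 1:2,
#'                 qt = c(0.24, 0.30), rt = c(0.20, 0.25),
#'                 st = c(0.16, 0.21), qr = c(0.04, 0.08),
#'                 rr = c(0.8, 0.8))
#' quality_filter(f)  # second beat rejected: qr > 0.075 s
#' @export
quality_filter <- function(features, qr_max = 0.075,
                           qt_rr_min = 0.200, qt_rr_max = 0.360,
                           rr_gate = TRUE, rr_min = 0.3, rr_max = 2.0) {
  stopifnot(is.data.frame(features))
  need <- c("qt", "qr", "rr")
  if (!all(need %in% names(features))) {
    stop("'features' must have columns ", paste(need, collapse = ", "))
  }
  reason <- rep(NA_character_, nrow(features))
  ratio <- features$qt / features$rr
  bad_qr <- features$qr > qr_max
  bad_ratio <- !(ratio > qt_rr_min & ratio < qt_rr_max)
  bad_rr <- if (rr_gate) {
    !(features$rr >= rr_min & features$rr <= rr_max)
  } else {
    rep(FALSE, nrow(features))
  }
  reason[bad_rr] <- "rr"
  reason[bad_ratio] <- "qt_rr"
  reason[bad_qr] <- "qr"          # first rule wins, so assign last
  acc <- is.na(reason)
  rejected <- features[!acc, , drop = FALSE]
  if (nrow(rejected)) rejected$reject_reason <- reason[!acc]
  else rejected$reject_reason <- character(0)
  rownames(rejected) <- NULL
  accepted <- features[acc, , drop = FALSE]
  rownames(accepted) <- NULL
  list(accepted = accepted, rejected = rejected)
}

#' Population mean RR interval
#'
#' The single normalization constant of the method: the arithmetic mean of
#' the preceding-RR intervals over all accepted training beats pooled across
#' subjects. One constant is produced per training run regardless of how many
#' subjects are enrolled.
#'
#' @param features a data frame of accepted beats with an `rr` column, or a
#'   numeric vector of RR intervals (s).
#' @return A single positive number (seconds).
#' @export
compute_rr_bar <- function(features) {
  rr <- if (is.data.frame(features)) features$rr else as.numeric(features)
  if (length(rr) == 0L) stop("cannot compute the mean RR of an empty set")
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("'rr' values must be positive")
  mean(rr)
}

#' Normalize interval features by the population mean RR
#'
#' Divides each of `qt`, `rt`, `st` by the single constant `rr_bar`. The
#' per-beat `rr` plays no role here: every beat -- training or test, whoever
#' it belongs to -- is mapped with the same constant, which is what lets a
#' single stored number project new beats into the training feature space.
#' Normalized features are dimensionless and inherit the beat ordering
#' `qt_n > rt_n > st_n`.
#'
#' @param features a data frame with columns `qt`, `rt`, `st` (and
#'   optionally `subject_id`, `beat_index`, which are carried through).
#' @param rr_bar positive scalar from [compute_rr_bar()].
#' @return A data frame with columns `subject_id`, `beat_index`, `qt_n`,
#'   `rt_n`, `st_n`.
#' @export
normalize_features <- function(features, rr_bar) {
  stopifnot(is.data.frame(features))
  if (!is.numeric(rr_bar) || length(rr_bar) != 1L || !is.finite(rr_bar) ||
      rr_bar <= 0) {
    stop("'rr_bar' must be a single positive number")
  }
  data.frame(
    subject_id = features$subject_id %||% rep(NA_character_, nrow(features)),
    beat_index = features$beat_index %||% seq_len(nrow(features)),
    qt_n = features$qt / rr_bar,
    rt_n = features$rt / rr_bar,
    st_n = features$st / rr_bar
  )
}

# Normalized feature matrix (n x 3) for the classifier.
feature_matrix <- function(normalized) {
  as.matrix(normalized[, c("qt_n", "rt_n", "st_n")])
}
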