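#' Construct a single-lead ECG record
#'
#' An `ecg_record` holds one lead of an ECG time series: an amplitude vector
#' in millivolts, the sampling rate in Hz, a subject label and an optional
#' lead name. Sample indices are 1-based; the time of sample `i` is
#' `t0 + (i - 1) / fs` seconds.
#'
#' @param samples numeric vector of amplitudes (mV); must be finite,
#'   length >= 1.
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id opaque subject label.
#' @param lead lead name, e.g. `"v5"`, or `NA`.
#' @param t0 start offset in seconds.
#' @return An object of class `ecg_record`.
#' @examples
#' r <- ecg_record(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), fs = 1000)
#' r
#' @export
ecg_record <- function(samples, fs, subject_id = "record", lead = NA_character_,
                       t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("'samples' must have length >= 1")
  if (!all(is.finite(samples))) stop("'samples' must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)")
  }
  structure(
    list(samples = samples, fs = fs, subject_id = as.character(subject_id),
         lead = lead, t0 = t0),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject '%s'%s: %d samples @ %g Hz (%.2f s)\n",
              x$subject_id,
              if (is.na(x$lead)) "" else paste0(", lead ", x$lead),
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

duration_s <- function(record) length(record$samples) / record$fs

as_record <- function(x, fs = NULL) {
  if (inherits(x, "ecg_record")) return(x)
  if (is.null(fs)) stop("'fs' is required when the input is a bare numeric vector")
  ecg_record(x, fs)
}

#' Read an ECG record from disk
#'
#' Two formats are supported. `"csv"` is the package's interchange format:
#' either one numeric amplitude per line, or two comma-separated columns
#' `time,amplitude` (an optional non-numeric header line is skipped). With a
#' single column `fs` must be supplied; with a time column `fs` is inferred
#' from the median sampling step when not given. `"wfdb"` reads a standard
#' WFDB header/signal pair (`.hea` plus format-16 or format-212 `.dat`) and
#' selects one named lead; amplitudes are converted to mV using the per-signal
#' gain and baseline.
#'
#' @param path file path (for `"wfdb"`, the `.hea` file or the record name
#'   without extension).
#' @param format `"csv"` or `"wfdb"`.
#' @param fs sampling rate in Hz; required for single-column CSV.
#' @param subject_id subject label; defaults to the file base name.
#' @param lead lead name to select (wfdb only); defaults to the first signal.
#' @return An [ecg_record()].
#' @seealso [write_ecg()]
#' @export
read_ecg <- function(path, format = c("csv", "wfdb"), fs = NULL,
                     subject_id = NULL, lead = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    read_ecg_csv(path, fs = fs, subject_id = subject_id, lead = lead)
  } else {
    read_ecg_wfdb(path, subject_id = subject_id, lead = lead)
  }
}

read_ecg_csv <- function(path, fs = NULL, subject_id = NULL, lead = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  first <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  data_lines <- if (has_header) lines[-1L] else lines
  offset <- if (has_header) 1L else 0L
  if (length(data_lines) == 0L) stop("no data rows in ", path)
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  ncol <- length(parts[[1L]])
  if (!ncol %in% c(1L, 2L)) {
    stop("expected 1 or 2 columns, found ", ncol, " in ", path)
  }
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- which(vapply(vals, function(v) length(v) != ncol || any(is.na(v)),
                      logical(1)))
  if (length(bad)) {
    stop(sprintf("non-numeric value on line %d of %s", bad[1L] + offset, path))
  }
  m <- do.call(rbind, vals)
  if (ncol == 1L) {
    if (is.null(fs)) stop("'fs' must be supplied for single-column CSV input")
    amp <- m[, 1L]
    t0 <- 0
  } else {
    amp <- m[, 2L]
    if (is.null(fs)) {
      if (nrow(m) < 2L) stop("'fs' must be supplied: cannot infer from one row")
      step <- median(diff(m[, 1L]))
      if (!is.finite(step) || step <= 0) stop("cannot infer 'fs' from time column")
      fs <- round(1 / step, 6)
    }
    t0 <- m[1L, 1L]
  }
  ecg_record(amp, fs,
             subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
             lead = lead %||% NA_character_, t0 = t0)
}

#' Write an ECG record as CSV
#'
#' Writes `time,amplitude` rows (full double precision, so a read/write round
#' trip reproduces the samples exactly) with a one-line header.
#'
#' @param record an [ecg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ecg <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  tt <- record$t0 + (seq_along(record$samples) - 1) / record$fs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,amplitude", con)
  writeLines(sprintf("%.17g,%.17g", tt, record$samples), con)
  invisible(path)
}

# Minimal WFDB reader: standard .hea plus format 16 (16-bit little-endian)
# or format 212 (packed 12-bit) .dat. Enough for PTB-style records.
read_ecg_wfdb <- function(path, subject_id = NULL, lead = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("header file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  n_sig <- as.integer(rec[[2L]])
  fs <- as.numeric(rec[[3L]])
  n_samp <- if (length(rec) >= 4L) as.integer(rec[[4L]]) else NA_integer_
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate in ", hea)
  sig <- lapply(lines[1L + seq_len(n_sig)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1L]]
    gain_tok <- tok[[3L]]
    gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gain_tok))
    baseline <- if (grepl("\\(", gain_tok)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_tok))
    } else 0
    desc <- if (length(tok) >= 9L) paste(tok[9:length(tok)], collapse = " ") else ""
    list(file = tok[[1L]], format = sub("x.*$", "", tok[[2L]]),
         gain = if (is.finite(gain) && gain != 0) gain else 200,
         baseline = baseline, desc = desc)
  })
  descs <- vapply(sig, `[[`, "", "desc")
  idx <- if (is.null(lead)) 1L else match(tolower(lead), tolower(descs))
  if (is.na(idx)) {
    stop("lead '", lead, "' not found; available: ", paste(descs, collapse = ", "))
  }
  fmt <- sig[[idx]]$format
  dat <- file.path(dirname(hea), sig[[idx]]$file)
  if (!file.exists(dat)) stop("signal file not found: ", dat)
  raw_n <- file.size(dat)
  adc <- if (fmt == "16") {
    all_v <- readBin(dat, "integer", n = raw_n / 2, size = 2,
                     endian = "little", signed = TRUE)
    matrix(all_v, ncol = n_sig, byrow = TRUE)[, idx]
  } else if (fmt == "212") {
    by <- as.integer(readBin(dat, "raw", n = raw_n))
    n_pairs <- length(by) %/% 3L
    b <- matrix(by[seq_len(3L * n_pairs)], nrow = 3L)
    v1 <- b[1L, ] + bitwShiftL(bitwAnd(b[2L, ], 15L), 8L)
    v2 <- b[3L, ] + bitwShiftL(bitwAnd(bitwShiftR(b[2L, ], 4L), 15L), 8L)
    v <- as.vector(rbind(v1, v2))
    v <- ifelse(v > 2047L, v - 4096L, v)
    matrix(v[seq_len((length(v) %/% n_sig) * n_sig)],
           ncol = n_sig, byrow = TRUE)[, idx]
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
  if (is.finite(n_samp) && n_samp > 0L) adc <- adc[seq_len(min(n_samp, length(adc)))]
  mv <- (adc - sig[[idx]]$baseline) / sig[[idx]]$gain
  ecg_record(mv, fs,
             subject_id = subject_id %||% sub("\\.hea$", "", basename(hea)),
             lead = if (nzchar(descs[idx])) descs[idx] else NA_character_)
}

#' Split a record into fixed-duration blocks
#'
#' Cuts a record into contiguous, non-overlapping blocks of `block_seconds`
#' numbered from 1 at the record start. A trailing remainder shorter than one
#' block is discarded. The evaluation protocol uses 10-second blocks, twelve
#' per 120-second record.
#'
#' @param record an [ecg_record()].
#' @param block_seconds block duration in seconds (> 0).
#' @return A list of `ecg_record` objects, each with elements `block_index`
#'   and `duration` added.
#' @examples
#' r <- ecg_record(rnorm(25000), fs = 1000)
#' length(slice_blocks(r, 10))  # 2 blocks, 5 s dropped
#' @export
slice_blocks <- function(record, block_seconds = 10) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.numeric(block_seconds) || block_seconds <= 0) {
    stop("'block_seconds' must be > 0")
  }
  bl <- round(block_seconds * record$fs)
  n <- length(record$samples)
  n_blocks <- n %/% bl
  if (n_blocks < 1L) {
    stop(sprintf("record (%.2f s) is shorter than one block (%g s)",
                 n / record$fs, block_seconds))
  }
  lapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1L) * bl + 1L):(b * bl)
    out <- ecg_record(record$samples[idx], record$fs,
                      subject_id = record$subject_id, lead = record$lead,
                      t0 = record$t0 + (idx[1L] - 1L) / record$fs)
    out$block_index <- b
    out$duration <- bl / record$fs
    out
  })
}

#' Write and read feature tables
#'
#' Feature tables (per-beat intervals or normalized features) are stored as
#' tab-separated text with a header row and full double precision, so a
#' write/read round trip reproduces numeric columns exactly.
#'
#' @param table a data frame of features.
#' @param path output path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns a data frame.
#' @export
write_features <- function(table, path) {
  stopifnot(is.data.frame(table))
  tab <- table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con)
  if (nrow(tab) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(tab)), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
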