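#' Enumerate train/test block combinations
#'
#' For `n_blocks` blocks per subject and `n_test` held-out test blocks,
#' produces one plan per unordered test-block combination (66 plans for the
#' default 12-choose-2). Each plan carries a seeded random permutation of
#' the remaining blocks as its training order; permutations are
#' rejection-sampled so that no training order repeats across plans.
#'
#' @param n_blocks number of blocks per subject.
#' @param n_test number of test blocks (< `n_blocks`).
#' @param seed integer seed for the training-order permutations.
#' @return A list of plans, each a list with `combo_id`, `test_blocks`
#'   (integer vector of length `n_test`) and `train_order` (permutation of
#'   the remaining blocks).
#' @examples
#' length(enumerate_splits(12, 2))  # 66
#' @export
enumerate_splits <- function(n_blocks = 12, n_test = 2, seed = 1L) {
  if (n_test >= n_blocks) stop("'n_test' must be smaller than 'n_blocks'")
  combos <- utils::combn(n_blocks, n_test)
  with_seed(seed, {
    seen <- character(0)
    lapply(seq_len(ncol(combos)), function(j) {
      test_blocks <- combos[, j]
      rest <- setdiff(seq_len(n_blocks), test_blocks)
      repeat {
        train_order <- rest[sample.int(length(rest))]
        key <- paste(train_order, collapse = ",")
        if (!key %in% seen) break
      }
      seen <<- c(seen, key)
      list(combo_id = j, test_blocks = test_blocks,
           train_order = train_order)
    })
  })
}

#' False acceptance and false rejection rates
#'
#' Verification-style error rates derived from the one-against-all binaries'
#' accept/reject decisions: for each class, its binary model should accept
#' (positive decision value) the genuine beats of that class and reject
#' everything else. Per class, `FRR = FN / (TP + FN)` over genuine beats and
#' `FAR = FP / (FP + TN)` over impostor beats; the returned rates are the
#' class averages expressed in percent. Classes with an empty genuine or
#' impostor set are omitted from the respective average with a warning.
#'
#' @param truth true class labels (one per beat).
#' @param decision decision-value matrix (beats x classes, columns named by
#'   class) as returned in the `"decision"` attribute of [predict.beatid()],
#'   or any matrix whose sign encodes accept/reject.
#' @return A list with `far` and `frr` (percent) and a per-class data frame
#'   `per_class`.
#' @examples
#' dm <- cbind(a = c(1, 1, -1, -1), b = c(-1, -1, 1, 1))
#' compute_far_frr(c("a", "a", "b", "b"), dm)  # perfect: 0 / 0
#' @export
compute_far_frr <- function(truth, decision) {
  decision <- rbind(decision)
  truth <- as.character(truth)
  if (is.null(colnames(decision))) stop("'decision' needs class column names")
  classes <- colnames(decision)
  per <- lapply(classes, function(k) {
    genuine <- truth == k
    acc <- decision[, k] > 0
    tp <- sum(genuine & acc); fn <- sum(genuine & !acc)
    fp <- sum(!genuine & acc); tn <- sum(!genuine & !acc)
    frr <- if (tp + fn > 0) 100 * fn / (tp + fn) else NA_real_
    far <- if (fp + tn > 0) 100 * fp / (fp + tn) else NA_real_
    data.frame(class = k, tp = tp, fn = fn, fp = fp, tn = tn,
               far = far, frr = frr)
  })
  per <- do.call(rbind, per)
  if (anyNA(per$far) || anyNA(per$frr)) {
    warning("classes without genuine or impostor beats omitted from the average")
  }
  list(far = mean(per$far, na.rm = TRUE), frr = mean(per$frr, na.rm = TRUE),
       per_class = per)
}

#' Mean number of beats until first correct identification
#'
#' Simulates the beat-to-beat identification procedure on a set of test
#' beats whose per-beat correctness is known: in each repetition the beats
#' are reshuffled, classified one at a time, and the attempt count at the
#' first correct identification is recorded; if no beat identifies the
#' subject the count equals the set size and the repetition is flagged
#' unidentified.
#'
#' @param correct logical vector: is each test beat classified correctly?
#' @param reps number of repetitions.
#' @return A list with `mean` (mean attempt count), `unidentified`
#'   (fraction of repetitions that exhausted the set) and `counts`.
#' @export
sim_beats_to_id <- function(correct, reps = 500) {
  n <- length(correct)
  if (n == 0L) stop("empty test set")
  hit <- logical(reps)
  counts <- numeric(reps)
  for (i in seq_len(reps)) {
    pos <- which(correct[sample.int(n)])[1L]
    hit[i] <- !is.na(pos)
    counts[i] <- if (hit[i]) pos else n   # exhaustion counts the full set
  }
  list(mean = mean(counts), unidentified = mean(!hit), counts = counts)
}

#' Beats-to-identification analysis for a fitted model
#'
#' For each subject, classifies that subject's accepted test beats with the
#' model, then runs [sim_beats_to_id()] over `reps` repetitions to estimate
#' how many randomly drawn beats (without replacement) are needed until the
#' subject is first identified correctly.
#'
#' @param model a fitted [beatid()] model.
#' @param features raw beat features of the test set (accepted beats),
#'   with a `subject_id` column.
#' @param reps repetitions per subject.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A list with `per_subject` (data frame: `subject_id`, `n_beats`,
#'   `mean_beats`, `unidentified`) and `mean_beats` (average over subjects).
#' @export
beats_to_identify <- function(model, features, reps = 500, seed = NULL) {
  stopifnot(inherits(model, "beatid"))
  if (nrow(features) == 0L) stop("empty test set")
  pred <- predict(model, features, apply_filter = FALSE)
  correct_all <- pred$label == as.character(features$subject_id)
  with_seed(seed, {
    subjects <- sort(unique(as.character(features$subject_id)))
    rows <- lapply(subjects, function(id) {
      corr <- correct_all[features$subject_id == id]
      if (length(corr) == 0L) {
        return(data.frame(subject_id = id, n_beats = 0L,
                          mean_beats = NA_real_, unidentified = NA_real_))
      }
      sim <- sim_beats_to_id(corr, reps = reps)
      data.frame(subject_id = id, n_beats = length(corr),
                 mean_beats = sim$mean, unidentified = sim$unidentified)
    })
    per <- do.call(rbind, rows)
    list(per_subject = per, mean_beats = mean(per$mean_beats, na.rm = TRUE))
  })
}

#' Speed-rate interval of an identification
#'
#' Converts a mean beats-to-identification count into a wall-clock decision
#' time range by multiplying with the extreme observed R-to-R intervals of
#' the test beats.
#'
#' @param mean_beats mean number of beats to identification (>= 1).
#' @param rr observed RR intervals of the test beats, s.
#' @return Named numeric vector `c(low, high)` in seconds.
#' @export
speed_rate <- function(mean_beats, rr) {
  if (length(rr) == 0L || any(!is.finite(rr))) stop("'rr' must be non-empty and finite")
  if (!is.numeric(mean_beats) || mean_beats < 1) stop("'mean_beats' must be >= 1")
  c(low = mean_beats * min(rr), high = mean_beats * max(rr))
}

#' Run the full block-resampling evaluation protocol
#'
#' Evaluates the identification pipeline the way an enrollment study would:
#' each subject's record is cut into `block_seconds` blocks; for every plan
#' from [enumerate_splits()] a model is trained on the first
#' `duration / block_seconds` blocks of the plan's training order (pooled
#' across subjects, with `rr_bar`, normalization and the cross-validated
#' grid search recomputed from that training set alone) and tested on the
#' plan's held-out test blocks of every subject. Training and test blocks
#' are asserted disjoint in every run. Metrics are averaged over plans per
#' training duration.
#'
#' @param records named list of [ecg_record()] objects (one per subject), or
#'   a cohort from [generate_cohort()].
#' @param durations training durations in seconds (multiples of
#'   `block_seconds`).
#' @param seed integer seed driving split enumeration, fold assignment and
#'   the beat-to-beat resampling.
#' @param grid_c,grid_sigma hyper-parameter grids for [cv_grid_search()].
#' @param folds cross-validation folds.
#' @param reps repetitions for [beats_to_identify()]; `0` skips that
#'   analysis.
#' @param block_seconds block length, s.
#' @param n_test number of test blocks per plan.
#' @param rr_gate apply the RR plausibility gate (see [quality_filter()]).
#' @param combos optional subset of plan `combo_id`s to run (default: all).
#' @param progress print one line per duration?
#' @return An object of class `beatid_protocol`: a data frame with one row
#'   per duration (accuracy, averaged-binary accuracy, FAR, FRR -- means and
#'   SDs across plans, in percent for the rates -- mean beats to
#'   identification and the speed-rate range), with the per-run long table
#'   in attribute `"runs"`.
#' @export
run_protocol <- function(records, durations = seq(10, 100, by = 10),
                         seed = 1L,
                         grid_c = c(0.01, 0.1, 1, 10, 50, 100, 150, 200),
                         grid_sigma = c(0.01, 0.1, 1, 10, 50, 100, 150, 200),
                         folds = 5, reps = 500, block_seconds = 10,
                         n_test = 2, rr_gate = TRUE, combos = NULL,
                         progress = FALSE) {
  if (!is.null(records$records)) records <- records$records
  if (is.null(names(records))) stop("'records' must be a named list")
  fs <- records[[1L]]$fs
  n_blocks <- min(vapply(records, function(r) {
    length(r$samples) %/% round(block_seconds * r$fs)
  }, numeric(1)))
  if (n_blocks <= n_test) stop("records too short for the requested split")
  if (any(durations %% block_seconds != 0) ||
      any(durations / block_seconds > n_blocks - n_test)) {
    stop("each duration must be a multiple of 'block_seconds' and leave ",
         n_test, " test blocks free")
  }

  feats <- cohort_features(records, rr_gate = rr_gate)$accepted
  if (nrow(feats) == 0L) stop("no accepted beats in the cohort")
  feats$block <- (feats$r_index - 1L) %/% round(block_seconds * fs) + 1L
  feats <- feats[feats$block <= n_blocks, , drop = FALSE]

  plans <- enumerate_splits(n_blocks, n_test, seed = seed)
  if (!is.null(combos)) {
    plans <- plans[vapply(plans, function(p) p$combo_id %in% combos,
                          logical(1))]
  }
  runs <- list()
  for (d in durations) {
    nb_train <- d / block_seconds
    for (p in plans) {
      train_blocks <- p$train_order[seq_len(nb_train)]
      stopifnot(length(intersect(train_blocks, p$test_blocks)) == 0L)
      train <- feats[feats$block %in% train_blocks, , drop = FALSE]
      test <- feats[feats$block %in% p$test_blocks, , drop = FALSE]
      stopifnot(length(intersect(train$r_index, test$r_index)) == 0L)
      # with very short training durations a subject can contribute fewer
      # beats than the fold count; shrink the folds rather than abort
      folds_use <- max(2L, min(folds, min(table(train$subject_id))))
      fit <- beatid(train, grid_c = grid_c, grid_sigma = grid_sigma,
                    folds = folds_use, seed = seed + 137L * p$combo_id)
      pred <- predict(fit, test, apply_filter = FALSE)
      dm <- attr(pred, "decision")
      truth <- as.character(test$subject_id)
      acc <- mean(pred$label == truth)
      acc_bin <- averaged_binary_accuracy(fit, test)
      ff <- compute_far_frr(truth, dm)
      bti <- if (reps > 0) {
        beats_to_identify(fit, test, reps = reps,
                          seed = seed + 137L * p$combo_id + 1L)$mean_beats
      } else NA_real_
      runs[[length(runs) + 1L]] <- data.frame(
        duration_s = d, combo_id = p$combo_id,
        chosen_c = fit$chosen_c, chosen_sigma = fit$chosen_sigma,
        cv_accuracy = fit$cv_accuracy, accuracy = acc,
        accuracy_binary = acc_bin, far = ff$far, frr = ff$frr,
        beats_to_id = bti,
        rr_min = min(test$rr), rr_max = max(test$rr))
    }
    if (progress) {
      message(sprintf("duration %3d s done (%d plans)", d, length(plans)))
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(durations, function(d) {
    r <- runs[runs$duration_s == d, , drop = FALSE]
    mb <- mean(r$beats_to_id)
    sr <- if (is.finite(mb)) {
      speed_rate(max(mb, 1), c(min(r$rr_min), max(r$rr_max)))
    } else c(low = NA_real_, high = NA_real_)
    data.frame(
      duration_s = d,
      accuracy_mean = mean(r$accuracy), accuracy_sd = sd(r$accuracy),
      accuracy_binary_mean = mean(r$accuracy_binary),
      accuracy_binary_sd = sd(r$accuracy_binary),
      far_mean = mean(r$far), far_sd = sd(r$far),
      frr_mean = mean(r$frr), frr_sd = sd(r$frr),
      mean_beats_to_id = mb,
      sr_low = unname(sr["low"]), sr_high = unname(sr["high"]))
  }))
  attr(agg, "runs") <- runs
  class(agg) <- c("beatid_protocol", "data.frame")
  agg
}

#' @export
print.beatid_protocol <- function(x, ...) {
  cat("Block-resampling evaluation (", nrow(attr(x, "runs")) / nrow(x),
      " runs per duration)\n", sep = "")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) round(v, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
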