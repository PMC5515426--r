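#' Fit a single-heartbeat identification model
#'
#' `beatid()` is the package's central fitting function. It takes accepted
#' per-beat interval features (see [compute_intervals()] and
#' [quality_filter()]) labelled by subject, computes the single normalization
#' constant `rr_bar` (the mean preceding-RR over all training beats pooled
#' across subjects), divides `qt`, `rt`, `st` by it, and trains one
#' soft-margin RBF-SVM per subject against all others (one-against-all).
#' When `c` or `sigma` is missing, the pair is selected from
#' `grid_c x grid_sigma` by stratified k-fold cross-validation
#' ([cv_grid_search()]); the default 8 x 8 grid spans
#' `{0.01, 0.1, 1, 10, 50, 100, 150, 200}` for both parameters.
#'
#' The kernel convention is `K(x, y) = exp(-||x - y||^2 / (2 sigma^2))`:
#' `sigma` is the Gaussian width, not the libsvm `gamma`. No per-feature
#' standardization is applied -- the division by `rr_bar` is the method's
#' entire normalization, which is why a deployed model stores exactly one
#' constant.
#'
#' @param features data frame of accepted beats with columns `subject_id`,
#'   `qt`, `rt`, `st`, `rr` (as produced by the feature pipeline).
#' @param c,sigma fixed hyper-parameters; when either is `NULL` both are
#'   chosen by cross-validation over the grids.
#' @param grid_c,grid_sigma candidate values for the grid search.
#' @param folds number of cross-validation folds.
#' @param seed integer seed for the stratified fold assignment.
#' @param rr_bar optional externally supplied normalization constant; by
#'   default computed from `features`.
#' @param tol dual-optimizer tolerance, passed to [fit_binary_svm()].
#' @return An object of class `beatid` with elements `classes`, `binaries`
#'   (one [fit_binary_svm()] model per class), `rr_bar`, `chosen_c`,
#'   `chosen_sigma`, `cv_accuracy` (`NA` when no search was run), `x`
#'   (normalized training matrix) and `y` (training labels).
#' @examples
#' coh <- generate_cohort(n_subjects = 3, duration_s = 30, fs = 500, seed = 1)
#' feats <- cohort_features(coh)
#' fit <- beatid(feats$accepted, c = 100, sigma = 0.1)
#' fit
#' @seealso [predict.beatid()], [run_protocol()]
#' @export
beatid <- function(features, c = NULL, sigma = NULL,
                   grid_c = c(0.01, 0.1, 1, 10, 50, 100, 150, 200),
                   grid_sigma = c(0.01, 0.1, 1, 10, 50, 100, 150, 200),
                   folds = 5, seed = 1L, rr_bar = NULL, tol = 1e-6) {
  stopifnot(is.data.frame(features))
  need <- c("subject_id", "qt", "rt", "st", "rr")
  if (!all(need %in% names(features))) {
    stop("'features' must have columns ", paste(need, collapse = ", "))
  }
  y <- as.character(features$subject_id)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 subjects to fit a model")
  rr_bar <- rr_bar %||% compute_rr_bar(features)
  norm <- normalize_features(features, rr_bar)
  x <- feature_matrix(norm)

  cv_accuracy <- NA_real_
  if (is.null(c) || is.null(sigma)) {
    gs <- cv_grid_search(x, y, grid_c = grid_c, grid_sigma = grid_sigma,
                         folds = folds, seed = seed, tol = tol)
    c <- gs$best_c
    sigma <- gs$best_sigma
    cv_accuracy <- gs$cv_accuracy
  }

  binaries <- lapply(classes, function(k) {
    fit_binary_svm(x, ifelse(y == k, 1, -1), c = c, sigma = sigma, tol = tol)
  })
  names(binaries) <- classes

  structure(
    list(classes = classes, binaries = binaries, rr_bar = rr_bar,
         chosen_c = c, chosen_sigma = sigma, cv_accuracy = cv_accuracy,
         x = x, y = y, call = match.call()),
    class = "beatid"
  )
}

#' Cross-validated grid search for the SVM hyper-parameters
#'
#' Evaluates every `(c, sigma)` pair of the grid by stratified k-fold
#' cross-validation of the full one-against-all scheme (a held-out beat is
#' counted correct when the binary model of its own subject attains the
#' maximal decision value). Ties are broken toward the smallest `c`, then
#' the smallest `sigma`.
#'
#' @param x normalized feature matrix (rows = beats).
#' @param y subject labels.
#' @param grid_c,grid_sigma candidate values.
#' @param folds number of folds; every class must have at least `folds`
#'   samples.
#' @param seed integer seed for the fold assignment.
#' @param tol dual-optimizer tolerance.
#' @return List with `best_c`, `best_sigma`, `cv_accuracy` and the full
#'   `table` of grid results.
#' @export
cv_grid_search <- function(x, y,
                           grid_c = c(0.01, 0.1, 1, 10, 50, 100, 150, 200),
                           grid_sigma = c(0.01, 0.1, 1, 10, 50, 100, 150, 200),
                           folds = 5, seed = 1L, tol = 1e-6) {
  x <- rbind(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  counts <- table(y)
  if (any(counts < folds)) {
    stop("every class needs at least ", folds, " samples for ", folds,
         "-fold cross-validation (smallest has ", min(counts), ")")
  }
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (k in classes) {
      idx <- which(y == k)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  grid <- expand.grid(c = sort(grid_c), sigma = sort(grid_sigma),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$c, grid$sigma), , drop = FALSE]
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      binaries <- lapply(classes, function(k) {
        fit_binary_svm(x[tr, , drop = FALSE], ifelse(y[tr] == k, 1, -1),
                       c = grid$c[g], sigma = grid$sigma[g], tol = tol)
      })
      dm <- oaa_decision_matrix(binaries, x[!tr, , drop = FALSE])
      pred <- classes[max.col(dm, ties.method = "first")]
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- which.max(acc)   # grid sorted by (c, sigma): first max wins ties
  list(best_c = grid$c[best], best_sigma = grid$sigma[best],
       cv_accuracy = acc[best],
       table = cbind(grid, cv_accuracy = acc))
}

#' Identify the subject of new beats
#'
#' Maps raw interval features of new beats into the training feature space
#' with the model's *stored* `rr_bar` (the per-beat `rr` is used only by the
#' plausibility filter) and assigns each beat to the class whose binary
#' decision value is maximal; ties go to the first class in the model's class
#' order.
#'
#' Beats that fail the plausibility filter are refused, not labelled: their
#' `label` is `NA` and `reject_reason` names the failed rule. Set
#' `apply_filter = FALSE` if the input is already filtered.
#'
#' @param object a fitted [beatid()] model.
#' @param newdata data frame of raw beat features (columns `qt`, `rt`, `st`,
#'   `qr`, `rr`).
#' @param apply_filter run [quality_filter()] on `newdata` first?
#' @param ... passed to [quality_filter()].
#' @return A data frame with one row per input beat: `label`, `accepted`,
#'   `reject_reason`, plus the decision values as attribute `"decision"`
#'   (matrix over accepted beats, columns = classes).
#' @export
predict.beatid <- function(object, newdata, apply_filter = TRUE, ...) {
  stopifnot(is.data.frame(newdata))
  n <- nrow(newdata)
  label <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  accepted <- rep(TRUE, n)
  if (apply_filter) {
    newdata$.row <- seq_len(n)
    qf <- quality_filter(newdata, ...)
    accepted <- seq_len(n) %in% qf$accepted$.row
    reason[qf$rejected$.row] <- qf$rejected$reject_reason
    use <- qf$accepted
  } else {
    use <- newdata
    use$.row <- seq_len(n)
  }
  dm <- NULL
  if (nrow(use) > 0L) {
    norm <- normalize_features(use, object$rr_bar)
    dm <- oaa_decision_matrix(object$binaries, feature_matrix(norm))
    label[use$.row] <- object$classes[max.col(dm, ties.method = "first")]
  }
  out <- data.frame(label = label, accepted = accepted,
                    reject_reason = reason)
  attr(out, "decision") <- dm
  out
}

#' Averaged binary accuracy of a one-against-all model
#'
#' For each per-class binary model, computes the accuracy of its
#' accept/reject (+1/-1) decision over the whole test set -- a beat of class
#' `k` should be accepted by binary `k` and rejected by all others -- and
#' returns the mean across classes. When every binary is perfect this equals
#' the argmax multiclass accuracy (both are 1).
#'
#' @param model a fitted [beatid()] model.
#' @param features raw beat features of the test set (already
#'   quality-filtered).
#' @param truth true subject labels; defaults to `features$subject_id`.
#' @return A scalar in `[0, 1]`.
#' @export
averaged_binary_accuracy <- function(model, features,
                                     truth = features$subject_id) {
  stopifnot(inherits(model, "beatid"))
  if (nrow(features) == 0L) stop("empty test set")
  norm <- normalize_features(features, model$rr_bar)
  dm <- oaa_decision_matrix(model$binaries, feature_matrix(norm))
  truth <- as.character(truth)
  accs <- vapply(seq_along(model$classes), function(j) {
    want <- ifelse(truth == model$classes[j], 1, -1)
    mean(sign(dm[, j]) == want | (dm[, j] == 0 & want == 1))
  }, numeric(1))
  mean(accs)
}

#' @export
print.beatid <- function(x, ...) {
  cat(sprintf("<beatid> %d subjects, C = %g, sigma = %g, rr_bar = %.4f s\n",
              length(x$classes), x$chosen_c, x$chosen_sigma, x$rr_bar))
  if (!is.na(x$cv_accuracy)) {
    cat(sprintf("  cross-validated accuracy: %.3f\n", x$cv_accuracy))
  }
  invisible(x)
}

#' @export
summary.beatid <- function(object, ...) {
  sv <- vapply(object$binaries, function(b) nrow(b$sv), integer(1))
  out <- list(classes = object$classes, n_train = nrow(object$x),
              support_points = sv, rr_bar = object$rr_bar,
              chosen_c = object$chosen_c, chosen_sigma = object$chosen_sigma,
              cv_accuracy = object$cv_accuracy)
  class(out) <- "summary.beatid"
  out
}

#' @export
print.summary.beatid <- function(x, ...) {
  cat(sprintf("One-against-all RBF-SVM over %d subjects (%d training beats)\n",
              length(x$classes), x$n_train))
  cat(sprintf("  rr_bar = %.4f s, C = %g, sigma = %g\n",
              x$rr_bar, x$chosen_c, x$chosen_sigma))
  if (!is.na(x$cv_accuracy)) {
    cat(sprintf("  cross-validated accuracy: %.3f\n", x$cv_accuracy))
  }
  cat("  support points per class:\n")
  print(x$support_points)
  invisible(x)
}

#' @export
coef.beatid <- function(object, ...) {
  lapply(object$binaries, function(b) {
    list(dual_coefs = b$dual_coefs, bias = b$bias)
  })
}

#' Plot the normalized training feature space
#'
#' Scatter plots of the three normalized features for every pair of axes,
#' colored by subject.
#'
#' @param x a fitted [beatid()] model.
#' @param ... passed to [graphics::pairs()].
#' @export
plot.beatid <- function(x, ...) {
  cl <- match(x$y, x$classes)
  pairs(x$x, col = cl, pch = 19,
        labels = c("QT / RRbar", "RT / RRbar", "ST / RRbar"), ...)
  invisible(x)
}

#' Save / load a fitted model as structured text
#'
#' The model is persisted as human-readable JSON (format version, classes,
#' per-class support points, dual coefficients and bias, the selected
#' hyper-parameters, and the single normalization constant `rr_bar`) at full
#' double precision, so a round trip reproduces predictions exactly.
#'
#' @param model a fitted [beatid()] model.
#' @param path file path.
#' @return `write_beatid()` returns `path` invisibly; `read_beatid()`
#'   returns the model.
#' @export
write_beatid <- function(model, path) {
  stopifnot(inherits(model, "beatid"))
  doc <- list(
    format = "beatid-model/1",
    classes = model$classes,
    rr_bar = model$rr_bar,
    c = model$chosen_c,
    sigma = model$chosen_sigma,
    cv_accuracy = model$cv_accuracy,
    binaries = lapply(model$binaries, function(b) {
      list(sv = b$sv, dual_coefs = b$dual_coefs, bias = b$bias)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_beatid
#' @export
read_beatid <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "beatid-model/1")) {
    stop("not a beatid model file: ", path)
  }
  binaries <- lapply(doc$binaries, function(b) {
    sv <- b$sv
    if (!is.matrix(sv)) sv <- matrix(unlist(sv), ncol = 3, byrow = TRUE)
    structure(list(sv = sv,
                   dual_coefs = as.numeric(b$dual_coefs),
                   bias = as.numeric(b$bias),
                   c = doc$c, sigma = doc$sigma, positive_class = 1),
              class = "binary_svm")
  })
  names(binaries) <- doc$classes
  structure(
    list(classes = doc$classes, binaries = binaries, rr_bar = doc$rr_bar,
         chosen_c = doc$c, chosen_sigma = doc$sigma,
         cv_accuracy = doc$cv_accuracy %||% NA_real_,
         x = NULL, y = NULL, call = NULL),
    class = "beatid"
  )
}
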