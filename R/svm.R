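#' Gaussian (RBF) kernel
#'
#' `exp(-||x - y||^2 / (2 sigma^2))`. Note the width convention: `sigma` is
#' the standard-deviation-like width of the Gaussian, so the `gamma` used by
#' libsvm-style interfaces is `1 / (2 sigma^2)`. Confusing the two changes
#' the meaning of every value on the hyper-parameter grid.
#'
#' @param x,y numeric vectors of equal length, or matrices with points in
#'   rows (`y` may have a different number of rows).
#' @param sigma positive kernel width.
#' @return A scalar in `(0, 1]` for vector input, otherwise the
#'   `nrow(x) x nrow(y)` kernel matrix.
#' @examples
#' rbf_kernel(c(0, 0, 0), c(1, 0, 0), sigma = 1 / sqrt(2))  # exp(-1)
#' @export
rbf_kernel <- function(x, y, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("'sigma' must be a single positive number")
  }
  if (is.matrix(x) || is.matrix(y)) {
    x <- rbind(x); y <- rbind(y)
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    d2[d2 < 0] <- 0
    exp(-d2 / (2 * sigma^2))
  } else {
    exp(-sum((x - y)^2) / (2 * sigma^2))
  }
}

#' Train one soft-margin binary RBF-SVM
#'
#' Solves the C-SVM dual (via libsvm) for labels in `{+1, -1}` with kernel
#' `exp(-||x - y||^2 / (2 sigma^2))`, keeping only the support points. The
#' decision value at a point `z` is
#' `sum_i dual_coefs[i] * K(sv[i], z) + bias`, positive for the `+1` class.
#' Dual coefficients are the signed `alpha_i * y_i`, bounded by `c` in
#' absolute value.
#'
#' @param x numeric matrix of training points (rows).
#' @param y labels, coercible to `{+1, -1}`; both classes must be present.
#' @param c regularization parameter C (> 0): the trade-off between margin
#'   maximization and training-error minimization.
#' @param sigma RBF width (> 0).
#' @param tol termination tolerance of the dual optimizer.
#' @return An object of class `binary_svm`: list with `sv` (support point
#'   matrix), `dual_coefs`, `bias`, `c`, `sigma`, `positive_class`.
#' @export
fit_binary_svm <- function(x, y, c, sigma, tol = 1e-6) {
  x <- rbind(x)
  y <- as.numeric(as.character(y))
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 / -1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (c <= 0 || sigma <= 0) stop("'c' and 'sigma' must be positive")
  fit <- e1071::svm(x, factor(y, levels = c(-1, 1)), scale = FALSE,
                    type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * sigma^2), cost = c, tolerance = tol)
  coefs <- as.numeric(fit$coefs)
  bias <- -fit$rho
  # libsvm's positive decision side is the first internal label; flip so
  # that positive always means the +1 class
  pos_level <- as.numeric(as.character(levels(factor(y, levels = c(-1, 1)))[
    fit$labels[1L]]))
  if (pos_level != 1) {
    coefs <- -coefs
    bias <- -bias
  }
  structure(
    list(sv = unname(as.matrix(fit$SV)), dual_coefs = coefs, bias = bias,
         c = c, sigma = sigma, positive_class = 1),
    class = "binary_svm"
  )
}

#' Decision values of a binary SVM
#'
#' @param model a `binary_svm` from [fit_binary_svm()].
#' @param x matrix of points (rows) to evaluate.
#' @return Numeric vector of decision values (positive = `+1` side).
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "binary_svm"))
  K <- rbf_kernel(rbind(x), model$sv, model$sigma)
  drop(K %*% model$dual_coefs) + model$bias
}

#' @export
print.binary_svm <- function(x, ...) {
  cat(sprintf("<binary_svm> %d support points, C = %g, sigma = %g\n",
              nrow(x$sv), x$c, x$sigma))
  invisible(x)
}

# Decision-value matrix (n x n_classes) of a one-against-all model list.
oaa_decision_matrix <- function(binaries, x) {
  x <- rbind(x)
  out <- vapply(binaries, decision_values, numeric(nrow(x)), x = x)
  matrix(out, nrow = nrow(x), dimnames = list(NULL, names(binaries)))
}
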