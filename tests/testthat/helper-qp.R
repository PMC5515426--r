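# Independent brute-force solver for the C-SVM dual, used as the oracle for
# the SVM implementation. For n points it enumerates all 3^n active-set
# assignments (alpha_i = 0, alpha_i = C, or 0 < alpha_i < C), solves the
# linear KKT system of each, and keeps the assignments whose solution
# satisfies every KKT condition. Only feasible for tiny n, which is the
# point: it shares no code path with the package's optimizer.

qp_svm_oracle <- function(x, y, C, sigma, tol = 1e-8) {
  x <- rbind(x)
  n <- nrow(x)
  stopifnot(n <= 8, all(y %in% c(-1, 1)))
  K <- exp(-as.matrix(dist(x))^2 / (2 * sigma^2))
  Q <- (y %o% y) * K

  best <- NULL
  states <- c("zero", "cap", "free")
  grid <- do.call(expand.grid,
                  c(rep(list(states), n), stringsAsFactors = FALSE))
  for (gi in seq_len(nrow(grid))) {
    st <- as.character(unlist(grid[gi, ]))
    free <- which(st == "free")
    cap <- which(st == "cap")
    alpha <- numeric(n)
    alpha[cap] <- C
    nf <- length(free)
    # unknowns: alpha[free], b;  equations: stationarity on free, y' alpha = 0
    A <- matrix(0, nf + 1, nf + 1)
    rhs <- numeric(nf + 1)
    if (nf > 0) {
      A[seq_len(nf), seq_len(nf)] <- Q[free, free, drop = FALSE]
      A[seq_len(nf), nf + 1] <- y[free]
      rhs[seq_len(nf)] <- 1 - Q[free, cap, drop = FALSE] %*% rep(C, length(cap))
    }
    A[nf + 1, seq_len(nf)] <- y[free]
    rhs[nf + 1] <- -sum(y[cap]) * C
    if (nf == 0) {
      # b unconstrained by equalities; feasible only if y' alpha = 0 already
      if (abs(rhs[nf + 1]) > tol) next
      # pick b from the inequality constraints' feasible interval
      g <- as.numeric(Q %*% alpha)
      lo <- -Inf; hi <- Inf
      for (i in seq_len(n)) {
        # zero: g_i + y_i b >= 1 ; cap: g_i + y_i b <= 1
        bnd <- (1 - g[i]) / y[i]
        if (st[i] == "zero") { if (y[i] > 0) lo <- max(lo, bnd) else hi <- min(hi, bnd) }
        else { if (y[i] > 0) hi <- min(hi, bnd) else lo <- max(lo, bnd) }
      }
      if (lo > hi + tol) next
      b <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2 else 0
    } else {
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      alpha[free] <- sol[seq_len(nf)]
      b <- sol[nf + 1]
      if (any(alpha[free] < -tol) || any(alpha[free] > C + tol)) next
      g <- as.numeric(Q %*% alpha)
      ok <- TRUE
      for (i in seq_len(n)) {
        m <- g[i] + y[i] * b
        if (st[i] == "zero" && m < 1 - 1e-6) ok <- FALSE
        if (st[i] == "cap" && m > 1 + 1e-6) ok <- FALSE
      }
      if (!ok) next
    }
    obj <- sum(alpha) - 0.5 * drop(t(alpha) %*% Q %*% alpha)
    if (is.null(best) || obj > best$obj + 1e-10) {
      best <- list(alpha = alpha, b = b, obj = obj)
    }
  }
  if (is.null(best)) stop("oracle found no KKT point")
  best
}

# decision values of the oracle solution at probe points
qp_decision <- function(oracle, x_train, y_train, sigma, z) {
  z <- rbind(z)
  x_train <- rbind(x_train)
  d2 <- outer(rowSums(z^2), rowSums(x_train^2), "+") - 2 * tcrossprod(z, x_train)
  d2[d2 < 0] <- 0
  Kz <- exp(-d2 / (2 * sigma^2))
  drop(Kz %*% (oracle$alpha * y_train)) + oracle$b
}

# Fixture datasets (<= 6 points, 3 dims) for the oracle-equivalence suite.
qp_fixtures <- function() {
  list(
    list(name = "mirror pair",
         x = rbind(c(-1, 0, 0), c(1, 0, 0)),
         y = c(1, -1), C = 100, sigma = 10),
    list(name = "xor",
         x = rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0)),
         y = c(1, 1, -1, -1), C = 100, sigma = 0.5),
    list(name = "separable 6",
         x = rbind(c(0.1, 0.2, 0.0), c(0.2, 0.1, 0.1), c(0.15, 0.25, 0.05),
                   c(0.9, 0.8, 1.0), c(1.0, 0.9, 0.9), c(0.85, 1.0, 0.95)),
         y = c(1, 1, 1, -1, -1, -1), C = 10, sigma = 1),
    list(name = "overlapping",
         x = rbind(c(0.0, 0.0, 0.0), c(0.2, 0.1, 0.0), c(0.35, 0.2, 0.1),
                   c(0.3, 0.25, 0.05), c(0.1, 0.3, 0.2), c(0.4, 0.1, 0.15)),
         y = c(1, 1, 1, -1, -1, -1), C = 1, sigma = 0.4),
    list(name = "unbalanced",
         x = rbind(c(0, 0, 0), c(0.1, 0, 0), c(1, 1, 1)),
         y = c(1, 1, -1), C = 5, sigma = 1)
  )
}
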