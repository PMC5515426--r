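test_that("the RBF kernel follows its closed form and symmetry", {
  expect_equal(rbf_kernel(c(1, 2, 3), c(1, 2, 3), sigma = 0.5), 1)
  expect_equal(rbf_kernel(c(0, 0, 0), c(1, 1, 0), sigma = 1), exp(-1))
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(3); b <- rnorm(3); s <- runif(1, 0.1, 2)
    expect_equal(rbf_kernel(a, b, s), rbf_kernel(b, a, s))
    expect_true(rbf_kernel(a, b, s) > 0 && rbf_kernel(a, b, s) <= 1)
  }
  expect_error(rbf_kernel(1:3, 1:3, sigma = 0), "positive")
  # matrix form agrees with the scalar form
  X <- matrix(rnorm(12), 4, 3)
  K <- rbf_kernel(X, X, 0.7)
  expect_equal(K[2, 3], rbf_kernel(X[2, ], X[3, ], 0.7))
})

test_that("binary SVM decision values match the brute-force QP solution", {
  probes <- rbind(c(0, 0, 0), c(0.5, 0.5, 0.5), c(0.2, -0.1, 0.3),
                  c(1, 1, 0), c(-0.5, 0.2, 0.1))
  for (fx in qp_fixtures()) {
    oracle <- qp_svm_oracle(fx$x, fx$y, fx$C, fx$sigma)
    fit <- fit_binary_svm(fx$x, fx$y, c = fx$C, sigma = fx$sigma)
    pts <- rbind(fx$x, probes)
    expect_lt(max(abs(decision_values(fit, pts) -
                        qp_decision(oracle, fx$x, fx$y, fx$sigma, pts))),
              1e-5, label = fx$name)
    expect_true(all(abs(fit$dual_coefs) <= fx$C + 1e-6))
  }
})

test_that("mirrored pair is separated symmetrically; XOR is learnable", {
  fit <- fit_binary_svm(rbind(c(-1, 0, 0), c(1, 0, 0)), c(1, -1),
                        c = 100, sigma = 10)
  expect_lt(abs(decision_values(fit, c(0, 0, 0))), 1e-6)

  x <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  y <- c(1, 1, -1, -1)
  fit <- fit_binary_svm(x, y, c = 100, sigma = 0.5)
  expect_equal(sign(decision_values(fit, x)), y)

  expect_error(fit_binary_svm(x, rep(1, 4), c = 1, sigma = 1), "classes")
  expect_error(fit_binary_svm(x[0, ], numeric(0), c = 1, sigma = 1))
})

test_that("decision function ignores training sample order", {
  feats <- small_features()$accepted
  fit1 <- beatid(feats, c = 10, sigma = 0.1)
  set.seed(123)
  perm <- sample(nrow(feats))
  fit2 <- beatid(feats[perm, ], c = 10, sigma = 0.1)
  probe <- feats[seq(1, nrow(feats), by = 7), ]
  p1 <- predict(fit1, probe, apply_filter = FALSE)
  p2 <- predict(fit2, probe, apply_filter = FALSE)
  expect_identical(p1$label, p2$label)
  expect_lt(max(abs(attr(p1, "decision") - attr(p2, "decision"))), 1e-6)
})

test_that("raising C on separable data never hurts training accuracy", {
  x <- rbind(matrix(rnorm(30, 0, 0.05), 10, 3),
             matrix(rnorm(30, 1, 0.05), 10, 3))
  y <- rep(c(1, -1), each = 10)
  accs <- vapply(c(0.01, 0.1, 1, 10, 100), function(C) {
    f <- fit_binary_svm(x, y, c = C, sigma = 1)
    mean(sign(decision_values(f, x)) == y)
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-12))
})

test_that("grid search evaluates the whole grid and breaks ties low", {
  feats <- small_features()$accepted
  norm <- normalize_features(feats, compute_rr_bar(feats))
  x <- as.matrix(norm[, c("qt_n", "rt_n", "st_n")])
  y <- norm$subject_id
  gs <- cv_grid_search(x, y, grid_c = c(1, 10), grid_sigma = c(0.01, 0.1),
                       folds = 3, seed = 4)
  expect_equal(nrow(gs$table), 4L)
  expect_equal(gs$cv_accuracy, max(gs$table$cv_accuracy))
  best_rows <- gs$table[gs$table$cv_accuracy == gs$cv_accuracy, ]
  expect_equal(gs$best_c, min(best_rows$c))
  expect_equal(gs$best_sigma,
               min(best_rows$sigma[best_rows$c == gs$best_c]))

  # full default grid has 64 pairs (checked without fitting via tiny data)
  xx <- rbind(matrix(rnorm(30, 0, 0.01), 10, 3),
              matrix(rnorm(30, 2, 0.01), 10, 3))
  yy <- rep(c("a", "b"), each = 10)
  gs2 <- cv_grid_search(xx, yy, folds = 2, seed = 1)
  expect_equal(nrow(gs2$table), 64L)
  expect_equal(gs2$cv_accuracy, 1)   # perfectly separated clusters

  # determinism under a fixed seed
  gs3 <- cv_grid_search(xx, yy, folds = 2, seed = 1)
  expect_identical(gs2[c("best_c", "best_sigma", "cv_accuracy")],
                   gs3[c("best_c", "best_sigma", "cv_accuracy")])
  expect_error(cv_grid_search(xx[1:11, ], yy[1:11], folds = 5),
               "5-fold")
})

test_that("one-against-all fit carries one binary per class and rr_bar", {
  feats <- study_features()$accepted
  fit <- fixture("study_fit", function() {
    beatid(feats, c = 100, sigma = 0.05)
  })
  expect_length(fit$binaries, 10L)
  expect_identical(names(fit$binaries), sort(unique(feats$subject_id)))
  expect_equal(fit$rr_bar, mean(feats$rr))
  expect_error(beatid(feats[feats$subject_id == "s01", ], c = 1, sigma = 1),
               "2 subjects")
})

test_that("two mirrored classes yield mirrored decision values", {
  base <- matrix(rnorm(45, 0, 0.3), 15, 3) + 1
  feats <- data.frame(subject_id = rep(c("a", "b"), each = 15),
                      qt = c(base[, 1], -base[, 1]),
                      rt = c(base[, 2], -base[, 2]),
                      st = c(base[, 3], -base[, 3]),
                      rr = 1)
  fit <- beatid(feats, c = 10, sigma = 1, rr_bar = 1)
  z <- matrix(rnorm(15, 0, 0.5), 5, 3)
  da <- decision_values(fit$binaries[["a"]], z)
  db <- decision_values(fit$binaries[["b"]], -z)
  expect_equal(da, db, tolerance = 1e-5)
})

test_that("prediction refuses implausible beats and breaks ties by order", {
  sv <- matrix(c(0.3, 0.25, 0.2), 1, 3)
  model <- toy_model(classes = c("a", "b"),
                     svs = list(sv, sv), coefs = list(1, 1),
                     biases = list(0, 0), sigma = 1, rr_bar = 1)
  ok <- feature_row(qt = 0.30, qr = 0.04, rr = 1)
  bad <- feature_row(qt = 0.30, qr = 0.09, rr = 1)
  pred <- predict(model, rbind(ok, bad))
  expect_identical(pred$label, c("a", NA_character_))  # tie -> first class
  expect_identical(pred$accepted, c(TRUE, FALSE))
  expect_identical(pred$reject_reason, c(NA_character_, "qr"))
})

test_that("a well-separated cohort identifies its own beats", {
  feats <- small_features()$accepted
  fit <- beatid(feats, c = 100, sigma = 0.1)
  pred <- predict(fit, feats, apply_filter = FALSE)
  expect_gte(mean(pred$label == feats$subject_id), 0.95)
})

test_that("averaged binary accuracy behaves like a mean of per-class rates", {
  # two classes, one binary always right, the other right 90% of the time
  x <- rbind(matrix(0, 10, 3), matrix(1, 10, 3))
  feats <- data.frame(subject_id = rep(c("a", "b"), each = 10),
                      qt = x[, 1], rt = x[, 2], st = x[, 3], rr = 1)
  fit <- beatid(feats, c = 100, sigma = 0.5, rr_bar = 1)
  expect_equal(averaged_binary_accuracy(fit, feats), 1)
  expect_error(averaged_binary_accuracy(fit, feats[0, ]), "empty")
})

test_that("model serialization round-trips predictions exactly", {
  feats <- small_features()$accepted
  fit <- beatid(feats, c = 10, sigma = 0.1)
  p <- withr::local_tempfile(fileext = ".json")
  write_beatid(fit, p)
  back <- read_beatid(p)
  set.seed(11)
  probes <- data.frame(qt = runif(100, 0.28, 0.34),
                       rt = runif(100, 0.24, 0.30),
                       st = runif(100, 0.20, 0.26),
                       rr = 1)
  d1 <- attr(predict(fit, probes, apply_filter = FALSE), "decision")
  d2 <- attr(predict(back, probes, apply_filter = FALSE), "decision")
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_identical(back$classes, fit$classes)
})
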