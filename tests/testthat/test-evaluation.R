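test_that("split enumeration covers every pair exactly once", {
  plans <- enumerate_splits(12, 2, seed = 3)
  expect_length(plans, 66L)
  keys <- vapply(plans, function(p) paste(sort(p$test_blocks), collapse = "-"),
                 character(1))
  expect_length(unique(keys), 66L)
  orders <- vapply(plans, function(p) paste(p$train_order, collapse = ","),
                   character(1))
  expect_length(unique(orders), 66L)  # no training order repeats
  for (p in plans) {
    expect_length(p$train_order, 10L)
    expect_length(intersect(p$test_blocks, p$train_order), 0L)
    expect_setequal(c(p$test_blocks, p$train_order), 1:12)
  }
  expect_length(enumerate_splits(3, 2, seed = 1), 3L)
  expect_error(enumerate_splits(2, 2), "smaller")
})

test_that("FAR and FRR are per-class rates averaged in percent", {
  # class a: TP = 9, FN = 1 over 10 genuine; FP = 1, TN = 89 over 90 impostors
  truth <- c(rep("a", 10), rep("b", 90))
  dec_a <- c(rep(1, 9), -1, 1, rep(-1, 89))
  dm <- cbind(a = dec_a, b = -dec_a)
  ff <- compute_far_frr(truth, dm)
  row_a <- ff$per_class[ff$per_class$class == "a", ]
  expect_equal(row_a$frr, 10)
  expect_equal(row_a$far, 100 * 1 / 90)

  perfect <- cbind(a = c(1, 1, -1), b = c(-1, -1, 1))
  ff2 <- compute_far_frr(c("a", "a", "b"), perfect)
  expect_equal(ff2$far, 0)
  expect_equal(ff2$frr, 0)

  all_rejected <- cbind(a = rep(-1, 4), b = rep(-1, 4))
  expect_warning(compute_far_frr(rep("a", 4), all_rejected),
                 "omitted")   # class b has no genuine beats
  ff3 <- suppressWarnings(compute_far_frr(rep("a", 4), all_rejected))
  expect_equal(ff3$per_class$frr[1], 100)
})

test_that("beat-to-beat resampling matches the exhaustion rules", {
  set.seed(5)
  always <- sim_beats_to_id(rep(TRUE, 8), reps = 200)
  expect_equal(always$mean, 1)
  expect_equal(always$unidentified, 0)

  never <- sim_beats_to_id(rep(FALSE, 5), reps = 200)
  expect_equal(never$mean, 5)
  expect_equal(never$unidentified, 1)

  expect_error(sim_beats_to_id(logical(0)), "empty")
})

test_that("resampled mean matches the analytic first-success expectation", {
  # m correct beats among n, sampled without replacement: the first success
  # position has expectation (n + 1) / (m + 1)
  set.seed(17)
  for (cfg in list(c(m = 5, n = 10), c(m = 2, n = 8), c(m = 9, n = 12))) {
    correct <- sample(rep(c(TRUE, FALSE), c(cfg["m"], cfg["n"] - cfg["m"])))
    sim <- sim_beats_to_id(correct, reps = 10000)
    expected <- (cfg["n"] + 1) / (cfg["m"] + 1)
    se <- sd(sim$counts) / sqrt(length(sim$counts))
    expect_lt(abs(sim$mean - expected), 3 * se + 1e-9)
  }
})

test_that("speed rate scales the observed RR extrema", {
  expect_equal(speed_rate(1, rep(0.8, 5)), c(low = 0.8, high = 0.8))
  sr <- speed_rate(1.02, c(0.588, 0.7, 1.176))
  expect_equal(unname(sr), c(1.02 * 0.588, 1.02 * 1.176), tolerance = 1e-12)
  expect_lte(sr["low"], sr["high"])
  expect_error(speed_rate(0.5, 0.8), ">= 1")
  expect_error(speed_rate(1, numeric(0)), "non-empty")
})

test_that("the protocol runs end-to-end, without leakage, reproducibly", {
  coh <- small_cohort()
  res1 <- run_protocol(coh, durations = 10, seed = 9,
                       grid_c = c(1, 100), grid_sigma = c(0.05, 0.5),
                       folds = 3, reps = 50, combos = c(1, 2, 3))
  expect_s3_class(res1, "beatid_protocol")
  expect_equal(nrow(res1), 1L)
  expect_true(res1$accuracy_mean >= 0 && res1$accuracy_mean <= 1)
  expect_true(all(res1$far_mean >= 0 & res1$far_mean <= 100))
  runs <- attr(res1, "runs")
  expect_equal(nrow(runs), 3L)
  expect_gte(res1$mean_beats_to_id, 1)

  res2 <- run_protocol(coh, durations = 10, seed = 9,
                       grid_c = c(1, 100), grid_sigma = c(0.05, 0.5),
                       folds = 3, reps = 50, combos = c(1, 2, 3))
  expect_identical(as.data.frame(res1), as.data.frame(res2))
  expect_identical(attr(res1, "runs"), attr(res2, "runs"))

  expect_error(run_protocol(coh, durations = 7, seed = 1), "multiple")
  expect_error(run_protocol(coh, durations = 30, seed = 1,
                            grid_c = 1, grid_sigma = 0.1),
               "test blocks free")  # 3 blocks of 10 s cannot spare 2 + 3
})

test_that("model-based beats-to-identification uses per-subject beats", {
  feats <- small_features()$accepted
  fit <- beatid(feats, c = 100, sigma = 0.1)
  bti <- beats_to_identify(fit, feats, reps = 100, seed = 3)
  expect_equal(nrow(bti$per_subject), 3L)
  expect_true(all(bti$per_subject$mean_beats >= 1))
  expect_lte(bti$mean_beats, 2)
})
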