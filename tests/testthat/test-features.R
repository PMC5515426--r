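test_that("interval arithmetic follows the fiducial indices", {
  fid <- data.frame(beat = 1:2,
                    q = c(60L, 100L + 700L - 40L),
                    r = c(100L, 100L + 700L),
                    s = c(140L, 100L + 700L + 40L),
                    t = c(360L, 100L + 700L + 260L),
                    valid = TRUE)
  iv <- compute_intervals(fid, fs = 1000, subject_id = "a")
  expect_equal(nrow(iv), 1L)          # first beat has no preceding R
  expect_equal(iv$qt, 0.300)
  expect_equal(iv$rt, 0.260)
  expect_equal(iv$st, 0.220)
  expect_equal(iv$qr, 0.040)
  expect_equal(iv$rr, 0.700)

  single <- compute_intervals(fid[1, ], fs = 1000)
  expect_equal(nrow(single), 0L)      # a lone beat yields nothing

  expect_error(compute_intervals(fid[2:1, ], fs = 1000), "ordered")
})

test_that("qt = qr + rt identically for fuzzed fiducial quadruples", {
  set.seed(99)
  n <- 10000
  fs <- 1000
  r <- cumsum(sample(300:2000, n, replace = TRUE))
  q <- r - sample(1:100, n, replace = TRUE)
  s <- r + sample(1:50, n, replace = TRUE)
  t <- r + sample(51:400, n, replace = TRUE)
  iv <- compute_intervals(data.frame(beat = seq_len(n), q = q, r = r,
                                     s = s, t = t, valid = TRUE), fs = fs)
  expect_equal(nrow(iv), n - 1L)
  # exact identity in sample units and to rounding noise in seconds
  expect_true(all((iv$qt - iv$qr - iv$rt) * fs == 0 |
                    abs(iv$qt - iv$qr - iv$rt) < 1e-12))
  expect_true(all(iv$qt > iv$rt & iv$rt > iv$st & iv$st > 0))
})

test_that("plausibility thresholds act exactly as printed", {
  # inclusive on QR = 0.075 s, strict on the QT/RR ratio bounds
  expect_equal(nrow(quality_filter(
    feature_row(qt = 0.24, qr = 0.080, rr = 0.8))$rejected), 1L)
  expect_equal(quality_filter(
    feature_row(qt = 0.24, qr = 0.080, rr = 0.8))$rejected$reject_reason, "qr")
  expect_equal(nrow(quality_filter(
    feature_row(qt = 0.250, qr = 0.040, rr = 1))$accepted), 1L)
  expect_equal(quality_filter(
    feature_row(qt = 0.360, qr = 0.040, rr = 1))$rejected$reject_reason,
    "qt_rr")
})

test_that("the filter partitions its input and is idempotent", {
  qf <- small_features()
  feats <- rbind(qf$accepted, qf$rejected[names(qf$accepted)])
  out <- quality_filter(feats)
  expect_equal(nrow(out$accepted) + nrow(out$rejected), nrow(feats))
  again <- quality_filter(out$accepted)
  expect_equal(nrow(again$rejected), 0L)
  expect_equal(again$accepted[names(out$accepted)], out$accepted)
  # optional RR gate: a beat passing the interval rules but outside the
  # physiological RR range is tagged "rr", and accepted when the gate is off
  wide <- feature_row(qt = 0.625, qr = 0.04, rr = 2.5)
  expect_equal(quality_filter(wide)$rejected$reject_reason, "rr")
  expect_equal(nrow(quality_filter(wide, rr_gate = FALSE)$accepted), 1L)
  # rule order: the interval ratio fires before the RR gate
  slow <- feature_row(qt = 0.24, qr = 0.04, rr = 2.5)
  expect_equal(quality_filter(slow)$rejected$reject_reason, "qt_rr")
})

test_that("the population RR mean is one pooled arithmetic mean", {
  expect_equal(compute_rr_bar(c(0.7, 0.9)), 0.8)
  expect_equal(compute_rr_bar(rep(0.85, 40)), 0.85)
  expect_error(compute_rr_bar(numeric(0)), "empty")

  # Monte-Carlo: generated RR intervals recover the template mean
  tpl <- subject_template(rr_mean_s = 0.75, rr_sd_s = 0.03)
  out <- generate_record(tpl, duration_s = 500, fs = 250, seed = 77)
  rr <- out$truth$rr[-1]
  expect_gt(length(rr), 500)
  se <- sd(rr) / sqrt(length(rr))
  expect_lt(abs(compute_rr_bar(rr) - 0.75), 3 * se)
})

test_that("normalization divides by one constant and is scale-invariant", {
  f <- feature_row(qt = 0.33, qr = 0.04, rr = 0.9, st = 0.30 - 0.04)
  f$st <- 0.30
  norm <- normalize_features(f, 0.75)
  expect_equal(norm$st_n, 0.40)
  ident <- normalize_features(f, 1)
  expect_equal(ident$qt_n, f$qt)

  qf <- small_features()
  feats <- qf$accepted
  rb <- compute_rr_bar(feats)
  n1 <- normalize_features(feats, rb)
  # uniform time dilation: all intervals and the constant scale together
  k <- 1.37
  dil <- feats
  dil[c("qt", "rt", "st", "qr", "rr")] <-
    dil[c("qt", "rt", "st", "qr", "rr")] * k
  n2 <- normalize_features(dil, compute_rr_bar(dil))
  expect_lt(max(abs(n1$qt_n - n2$qt_n)), 1e-9)
  expect_lt(max(abs(n1$rt_n - n2$rt_n)), 1e-9)
  expect_lt(max(abs(n1$st_n - n2$st_n)), 1e-9)

  # ordering is preserved by the positive constant
  expect_true(all(n1$qt_n > n1$rt_n & n1$rt_n > n1$st_n))
  expect_error(normalize_features(feats, -1), "positive")
})
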