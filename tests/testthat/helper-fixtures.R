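# Shared fixtures, built lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small, fast cohort for unit tests (3 subjects, 30 s, 500 Hz).
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(n_subjects = 3, separation = 6, duration_s = 30,
                    fs = 500, seed = 301)
  })
}

small_features <- function() {
  fixture("small_features", function() cohort_features(small_cohort()))
}

# The study-scale cohort used by the acceptance checks
# (10 subjects, 120 s, 1000 Hz, separation 5 x timing noise SD).
study_cohort <- function() {
  fixture("study_cohort", function() {
    generate_cohort(n_subjects = 10, separation = 5, duration_s = 120,
                    fs = 1000, seed = 11)
  })
}

study_features <- function() {
  fixture("study_features", function() cohort_features(study_cohort()))
}

# A bare bump train: R-like gaussians at given anchor times (s).
bump_train <- function(anchors, fs, duration_s, amp = 1, width = 0.012) {
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  for (a in anchors) sig <- sig + amp * exp(-(tt - a)^2 / (2 * width^2))
  ecg_record(sig, fs)
}

# Hand-built feature rows for filter tests.
feature_row <- function(qt, qr, rr, rt = qt - qr, st = rt - 0.03,
                        subject_id = "x", beat_index = 1L) {
  data.frame(subject_id = subject_id, beat_index = beat_index,
             qt = qt, rt = rt, st = st, qr = qr, rr = rr)
}

# A hand-built one-against-all model (no optimizer involved), for tie-break
# and refusal tests.
toy_model <- function(classes = c("a", "b"), svs, coefs, biases,
                      sigma = 1, rr_bar = 1) {
  binaries <- lapply(seq_along(classes), function(i) {
    structure(list(sv = svs[[i]], dual_coefs = coefs[[i]], bias = biases[[i]],
                   c = 1, sigma = sigma, positive_class = 1),
              class = "binary_svm")
  })
  names(binaries) <- classes
  structure(list(classes = classes, binaries = binaries, rr_bar = rr_bar,
                 chosen_c = 1, chosen_sigma = sigma, cv_accuracy = NA_real_,
                 x = NULL, y = NULL, call = NULL),
            class = "beatid")
}
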