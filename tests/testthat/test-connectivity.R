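# Magnitude coherence estimator, FC matrices, dynamic features and the
# paired state comparison.

test_that("self-coherence is exactly 1 and scale invariance holds", {
  set.seed(1)
  x <- rnorm(1000)
  expect_equal(coherence_pair(x, x, fs = 100), 1)
  y <- rnorm(1000)
  c0 <- coherence_pair(x, y, fs = 100)
  expect_equal(coherence_pair(3.7 * x, -0.2 * y, fs = 100), c0)
})

test_that("the estimator matches a brute-force DFT implementation", {
  set.seed(2)
  fs <- 32 # 64-sample toys: 2-s signals, 1-s segments
  for (i in 1:4) {
    x <- rnorm(64)
    y <- 0.5 * x + rnorm(64)
    est <- coherence_pair(x, y, fs = fs, band = c(1, 15))
    oracle <- brute_coherence(x, y, fs = fs, band = c(1, 15))
    expect_lt(abs(est - oracle), 1e-10)
  }
})

test_that("coherence stays in [0, 1] on arbitrary signals", {
  set.seed(3)
  for (i in 1:200) {
    n <- sample(150:400, 1)
    fs <- sample(c(32, 50, 64), 1)
    x <- rnorm(n) * runif(1, 0.1, 100)
    y <- rnorm(n) * runif(1, 0.1, 100) + runif(1, 0, 0.5) * x
    v <- coherence_pair(x, y, fs = fs, band = c(1, fs / 2 - 1))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("independent noise sits near the K-segment bias floor", {
  set.seed(4)
  fs <- 100
  vals <- vapply(1:20, function(i) {
    x <- rnorm(10 * fs) # K = 19 one-second segments at 50% overlap
    y <- rnorm(10 * fs)
    coherence_pair(x, y, fs = fs)
  }, numeric(1))
  expect_true(all(vals < 0.35))
  expect_gt(mean(vals), 0.1) # the floor is positive, not zero
})

test_that("too-short signals error rather than degenerate to 1", {
  expect_error(coherence_pair(rnorm(80), rnorm(80), fs = 64),
    class = "emofc_config_error"
  )
})

test_that("trial FC matrices are symmetric, unit-diagonal, complete", {
  set.seed(5)
  seg <- matrix(rnorm(8 * 500), 8,
    dimnames = list(frontal_subset(), NULL)
  )
  m <- trial_fc_matrix(seg, fs = 100)
  expect_equal(dim(m), c(8, 8))
  expect_equal(unname(diag(m)), rep(1, 8))
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  expect_equal(nrow(tidy(m)), 28)
  dup <- seg
  dup["Fpz", ] <- dup["Fp1", ]
  m2 <- trial_fc_matrix(dup, fs = 100)
  expect_equal(m2["Fp1", "Fpz"], 1)
  expect_error(
    trial_fc_matrix(seg[1:3, ], channels = frontal_subset(), fs = 100),
    class = "emofc_config_error"
  )
})

test_that("dynamic features concatenate chronological class trials", {
  set.seed(6)
  mk <- function() {
    m <- matrix(runif(16), 4)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(letters[1:4], letters[1:4])
    m
  }
  fc <- tibble::tibble(
    subject = rep(1:2, each = 4),
    label = rep(c("HVA", "HVA", "LVA", "LVA"), 2),
    class_trial = rep(c(1, 2, 1, 2), 2),
    fc = replicate(8, mk(), simplify = FALSE)
  )
  f1 <- dynamic_fc_features(fc, k = 1)
  expect_equal(nrow(f1), 4) # 2 subjects x 2 states
  expect_true(all(vapply(
    f1$image, function(m) ncol(m) == 4,
    logical(1)
  )))
  f2 <- dynamic_fc_features(fc, k = 2)
  expect_true(all(vapply(
    f2$image, function(m) ncol(m) == 8,
    logical(1)
  )))
  # prefix property: permuting later trials leaves k = 1 unchanged
  fc_perm <- fc
  fc_perm$fc[fc_perm$class_trial == 2] <-
    rev(fc_perm$fc[fc_perm$class_trial == 2])
  f1p <- dynamic_fc_features(fc_perm, k = 1)
  expect_identical(f1$image, f1p$image)
  expect_warning(
    f3 <- dynamic_fc_features(fc[-1, ], k = 2),
    "skipped"
  )
  expect_equal(nrow(f3), 3)
  expect_error(suppressWarnings(dynamic_fc_features(fc, k = 5)))
})

test_that("identical states compare as t = 0, p = 1", {
  mk <- function() {
    m <- matrix(0.4, 3, 3)
    diag(m) <- 1
    dimnames(m) <- list(letters[1:3], letters[1:3])
    m
  }
  fc <- tibble::tibble(
    subject = rep(1:4, each = 2),
    label = rep(c("HVA", "LVA"), 4),
    class_trial = 1,
    fc = replicate(8, mk(), simplify = FALSE)
  )
  cmp <- compare_fc_states(fc)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_equal(glance(cmp)$hva_mean_fc, 0.4, tolerance = 1e-12)
})

test_that("the Fisher transform and clipping behave as documented", {
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  mk <- function(v) {
    m <- matrix(v, 2, 2)
    diag(m) <- 1
    dimnames(m) <- list(c("a", "b"), c("a", "b"))
    m
  }
  fc <- tibble::tibble(
    subject = rep(1:2, each = 2),
    label = rep(c("HVA", "LVA"), 2),
    class_trial = 1,
    fc = list(mk(1), mk(0.5), mk(0.3), mk(0.5)) # an off-diagonal at 1
  )
  expect_warning(cmp <- compare_fc_states(fc), "clipped")
  expect_true(is.finite(cmp$t))
})

test_that("a planted state contrast is detected across subjects", {
  cfg <- eeg_protocol(
    n_subjects = 8, n_trials_per_class = 3, rest_s = 1,
    stim_s = 20, fs = 128, seed = 31, channel_labels = frontal_montage()
  )
  fc <- dplyr::bind_rows(lapply(seq_len(cfg$n_subjects), function(s) {
    rec <- simulate_subject(cfg, plant_spec(), s)
    fc_dataset(segment_trials(rec, stim_s = 20, baseline_s = 1),
      channels = frontal_subset(), fs = cfg$fs
    )
  }))
  cmp <- compare_fc_states(fc)
  g <- glance(cmp)
  expect_gt(g$lva_mean_fc, g$hva_mean_fc) # planted LVA > HVA direction
  expect_lt(cmp$p, 0.05)
  td <- tidy(cmp)
  expect_equal(nrow(td), 8)
})
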