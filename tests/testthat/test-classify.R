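# Fold construction, confusion counts, metrics, baselines.

test_that("fivefold rotation reproduces the per-class data budget", {
  labels <- rep(c("HVA", "LVA"), each = 1800)
  folds <- make_folds(labels, k = 5, seed = 1)
  for (f in 1:5) {
    sp <- fold_split(folds, f)
    lab <- folds$label
    expect_equal(sum(lab[sp$train] == "HVA"), 1080)
    expect_equal(sum(lab[sp$val] == "HVA"), 360)
    expect_equal(sum(lab[sp$test] == "HVA"), 360)
    expect_equal(sum(lab[sp$test] == "LVA"), 360)
  }
})

test_that("small sets split in the same ratios and test parts tile", {
  labels <- rep(c("HVA", "LVA"), each = 10)
  folds <- make_folds(labels, k = 5, seed = 2)
  sp <- fold_split(folds, 3)
  expect_equal(sum(folds$label[sp$train] == "HVA"), 6)
  expect_equal(sum(folds$label[sp$val] == "HVA"), 2)
  expect_equal(sum(folds$label[sp$test] == "HVA"), 2)
  tested <- sort(unlist(lapply(1:5, function(f) fold_split(folds, f)$test)))
  expect_equal(tested, seq_along(labels)) # exhaustive partition
  expect_error(make_folds(labels, k = 2), class = "emofc_config_error")
})

test_that("confusion counts behave under canonical predictors", {
  truth <- rep(c("HVA", "LVA"), each = 5)
  perfect <- confusion_counts(truth, truth)
  expect_equal(perfect$FP + perfect$FN, 0)
  const <- confusion_counts(truth, rep("HVA", 10))
  expect_equal(unlist(const[c("TP", "FP", "TN", "FN")]),
    c(TP = 5, FP = 5, TN = 0, FN = 0)
  )
  inverted <- confusion_counts(
    truth,
    ifelse(truth == "HVA", "LVA", "HVA")
  )
  expect_equal(inverted$TP, perfect$FN)
  expect_equal(inverted$FN, perfect$TP)
  expect_error(confusion_counts(truth, rep("bad", 10)),
    class = "emofc_config_error"
  )
})

test_that("metrics reproduce hand-computed values and identities", {
  m <- compute_metrics(list(TP = 30, FN = 10, TN = 35, FP = 5))
  expect_equal(m$accuracy, 81.25)
  expect_equal(m$sensitivity, 75)
  expect_equal(m$specificity, 87.5)
  expect_equal(m$f1, 80)
  perfect <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_true(all(perfect[1, ] == 100))
  # accuracy invariant to class swap; sensitivity + miss rate = 100
  sw <- compute_metrics(list(TP = 35, FN = 5, TN = 30, FP = 10))
  expect_equal(sw$accuracy, m$accuracy)
  expect_equal(m$sensitivity + (100 - m$sensitivity), 100)
})

test_that("undefined metrics are NA, never zero", {
  m <- compute_metrics(list(TP = 0, FN = 10, TN = 10, FP = 0))
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 100)
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
    class = "emofc_config_error"
  )
})

test_that("baselines separate an easy set and are seed-deterministic", {
  s <- make_separable_samples(40, seed = 9)
  cv_svm <- cross_validate(s, model = "svm", k = 5, seed = 1)
  expect_gt(mean(cv_svm$accuracy), 90)
  cv_rf <- cross_validate(s, model = "rf", k = 5, seed = 1)
  expect_gt(mean(cv_rf$accuracy), 90)
  cv_svm2 <- cross_validate(s, model = "svm", k = 5, seed = 1)
  expect_identical(cv_svm$accuracy, cv_svm2$accuracy)
  perm <- s
  set.seed(10)
  perm$label <- sample(rep(c("HVA", "LVA"), each = 40))
  cv_perm <- cross_validate(perm, model = "svm", k = 5, seed = 1)
  expect_lt(mean(cv_perm$accuracy), 65)
  expect_error(train_baseline("svm", list(), character(0)),
    class = "emofc_config_error"
  )
})

test_that("cv_result summaries report mean and SD per metric", {
  s <- make_separable_samples(25, seed = 12)
  cv <- cross_validate(s, model = "svm", k = 5, seed = 3)
  expect_s3_class(cv, "cv_result")
  expect_equal(nrow(cv), 5)
  g <- glance(cv)
  expect_equal(g$accuracy_mean, mean(cv$accuracy))
  expect_equal(g$accuracy_sd, sd(cv$accuracy))
  td <- tidy(cv)
  expect_equal(nrow(td), 25) # 5 folds x 5 metrics
})

test_that("channel subsets re-encode from the raw sample matrices", {
  cfg <- eeg_protocol(
    n_subjects = 1, n_trials_per_class = 2, rest_s = 1,
    stim_s = 3, fs = 100, seed = 3, channel_labels = frontal_montage()
  )
  rec <- simulate_subject(cfg, plant_spec(), 1)
  samples <- encode_samples(window_per_second(segment_trials(rec,
    stim_s = 3, baseline_s = 1
  ), cfg$fs))
  sub <- c("Fp1", "F7")
  cv <- cross_validate(samples, model = "svm", k = 3, seed = 1,
    channels = sub)
  expect_s3_class(cv, "cv_result")
  expect_error(
    cross_validate(samples, model = "svm", channels = c("Fp1", "XX")),
    class = "emofc_config_error"
  )
})

test_that("grouped splits keep a subject's or trial's samples together", {
  s <- make_separable_samples(30, seed = 13)
  s$subject <- rep(1:6, length.out = nrow(s))
  s$trial <- rep(1:12, length.out = nrow(s))
  for (mode in c("subject", "trial")) {
    cv <- cross_validate(s, model = "svm", k = 3, seed = 2,
      split_by = mode)
    expect_equal(nrow(cv), 3)
  }
})
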