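# Filtering, re-referencing, artifact regression and segmentation.

tone_rec <- function(freq, fs = 500, dur = 10, n_ch = 1) {
  t <- seq_len(dur * fs) / fs
  data <- matrix(rep(sin(2 * pi * freq * t), n_ch),
    nrow = n_ch,
    byrow = TRUE, dimnames = list(paste0("ch", seq_len(n_ch)), NULL)
  )
  eeg_recording(data, fs, rownames(data), tibble::tibble(
    onset = integer(), trial = integer(), class_trial = integer(),
    label = character()
  ))
}

# steady-state gain: RMS over the interior, away from the ~1 s edge
# transient any finite zero-phase filter carries
interior_rms <- function(rec, fs = rec$fs) {
  n <- ncol(rec$data)
  sqrt(mean(rec$data[1, (fs + 1):(n - fs)]^2))
}

test_that("notch removes 50 Hz by >= 30 dB and passes 10 Hz within 1%", {
  rec50 <- tone_rec(50)
  out50 <- notch_filter(rec50)
  expect_lt(interior_rms(out50) / interior_rms(rec50), 0.032)
  rec10 <- tone_rec(10)
  out10 <- notch_filter(rec10)
  expect_lt(abs(interior_rms(out10) / interior_rms(rec10) - 1), 0.01)
  zero <- tone_rec(10)
  zero$data[] <- 0
  expect_equal(notch_filter(zero)$data, zero$data)
  expect_error(
    notch_filter(tone_rec(50, fs = 100)),
    class = "emofc_config_error"
  )
})

test_that("bandpass attenuates 60 Hz and DC, preserves 10 Hz", {
  out60 <- bandpass_filter(tone_rec(60))
  expect_lt(interior_rms(out60) / interior_rms(tone_rec(60)), 0.032)
  out10 <- bandpass_filter(tone_rec(10))
  expect_lt(abs(interior_rms(out10) / interior_rms(tone_rec(10)) - 1),
    0.01)
  dc <- tone_rec(10)
  dc$data[] <- 100
  outdc <- bandpass_filter(dc)
  n <- ncol(outdc$data)
  expect_lt(max(abs(outdc$data[1, 500:(n - 500)])), 1)
})

test_that("zero-phase filtering leaves a passband tone at lag zero", {
  rec <- tone_rec(10)
  out <- bandpass_filter(rec)
  cc <- ccf(out$data[1, ], rec$data[1, ], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  out2 <- notch_filter(rec)
  cc2 <- ccf(out2$data[1, ], rec$data[1, ], lag.max = 20, plot = FALSE)
  expect_equal(cc2$lag[which.max(cc2$acf)], 0)
})

test_that("notch and bandpass commute on noise (LTI order invariance)", {
  set.seed(1)
  rec <- tone_rec(10, dur = 8)
  rec$data[1, ] <- rnorm(ncol(rec$data))
  a <- bandpass_filter(notch_filter(rec))$data[1, ]
  b <- notch_filter(bandpass_filter(rec))$data[1, ]
  keep <- 1000:(length(a) - 1000) # interior, away from edge padding
  rel <- sqrt(mean((a[keep] - b[keep])^2)) / sqrt(mean(a[keep]^2))
  expect_lt(rel, 1e-6)
})

test_that("common average reference zeroes the analysis-channel mean", {
  data <- matrix(c(1, 3), 2, 10, dimnames = list(c("a", "b"), NULL))
  rec <- eeg_recording(data, 100, c("a", "b"), tibble::tibble(
    onset = integer(), trial = integer(), class_trial = integer(),
    label = character()
  ))
  out <- common_average_reference(rec, c("a", "b"))
  expect_equal(out$data[1, ], rep(-1, 10))
  expect_equal(out$data[2, ], rep(1, 10))

  set.seed(2)
  rec$data <- matrix(rnorm(20), 2)
  out <- common_average_reference(rec, c("a", "b"))
  expect_lt(max(abs(colMeans(out$data))), 1e-9)

  single <- common_average_reference(rec, "a")
  expect_equal(single$data[1, ], rep(0, 10))
  expect_error(common_average_reference(rec, character(0)),
    class = "emofc_config_error"
  )
  # M1/M2 are excluded by default and left untouched
  cfg <- eeg_protocol(
    n_subjects = 1, n_trials_per_class = 1, rest_s = 1,
    stim_s = 2, fs = 100, seed = 2, channel_labels = frontal_montage()
  )
  rec2 <- simulate_subject(cfg, plant_spec(), 1)
  out2 <- common_average_reference(rec2)
  expect_identical(out2$data["M1", ], rec2$data["M1", ])
  expect_lt(max(abs(colMeans(out2$data[frontal_subset(), ]))), 1e-9)
})

test_that("artifact regression removes exactly the projected component", {
  set.seed(3)
  n <- 2000
  art <- as.numeric(arima.sim(list(ar = 0.95), n))
  ac <- art - mean(art)
  noise <- rnorm(n)
  noise <- noise - ac * sum(noise * ac) / sum(ac^2) # orthogonalize
  data <- rbind(
    mixed = 2 * art + noise,
    clean = noise
  )
  rec <- eeg_recording(data, 100, rownames(data), tibble::tibble(
    onset = integer(), trial = integer(), class_trial = integer(),
    label = character()
  ))
  out <- remove_artifact(rec, art)
  expect_lt(abs(cor(out$data["mixed", ], art)), 0.01)
  expect_lt(max(abs(out$data["clean", ] - noise)), 1e-9)
  rec$data["mixed", ] <- art
  out2 <- remove_artifact(rec, art)
  expect_lt(sd(out2$data["mixed", ]), 1e-9)
  expect_error(remove_artifact(rec, rep(1, n)),
    class = "emofc_config_error"
  )
})

test_that("segmentation baselines and skips edge-incomplete events", {
  fs <- 100
  data <- matrix(rnorm(3 * 30 * fs), 3,
    dimnames = list(c("a", "b", "c"), NULL)
  )
  data[2, ] <- 7 # constant channel
  events <- tibble::tibble(
    onset = c(1L, 600L, 1600L, 2950L),
    trial = 1:4, class_trial = c(1L, 1L, 2L, 2L),
    label = c("HVA", "HVA", "LVA", "LVA")
  )
  rec <- eeg_recording(data, fs, rownames(data), events)
  expect_warning(
    segs <- segment_trials(rec, stim_s = 2, baseline_s = 1),
    "skipping 2"
  )
  expect_equal(nrow(segs), 2) # events at sample 1 and near the end dropped
  expect_equal(dim(segs$data[[1]]), c(3, 2 * fs))
  expect_equal(unname(segs$data[[1]][2, ]), rep(0, 2 * fs))
  expect_lt(max(abs(rowMeans(segs$baseline[[1]]))), 1e-12)
})

test_that("the default protocol segments into 12 trials per subject", {
  cfg <- eeg_protocol(
    n_subjects = 1, fs = 128, seed = 21,
    channel_labels = frontal_montage()
  )
  rec <- simulate_subject(cfg, plant_spec(), 1)
  segs <- preprocess_recording(rec)
  expect_equal(nrow(segs), 12)
  expect_equal(sort(unique(segs$label)), c("HVA", "LVA"))
  expect_equal(dim(segs$data[[1]]), c(10, 20 * cfg$fs))
})
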