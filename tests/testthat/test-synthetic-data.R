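# Synthetic EEG generator: protocol arithmetic, determinism, planted
# statistical structure.

test_that("default protocol yields 12 stimulation events per subject", {
  cfg <- eeg_protocol(n_subjects = 1, fs = 100, seed = 3)
  rec <- simulate_subject(cfg, plant_spec(), 1)
  expect_equal(nrow(rec$events), 12)
  expect_equal(sum(rec$events$label == "HVA"), 6)
  expect_equal(
    ncol(rec$data),
    12 * (2 * cfg$rest_s + cfg$stim_s) * cfg$fs
  )
  expect_equal(rec$labels, montage_32())
})

test_that("a minimal protocol gives 2 events and 2 s of signal", {
  cfg <- eeg_protocol(
    n_subjects = 1, n_trials_per_class = 1, rest_s = 0,
    stim_s = 1, fs = 100, seed = 1
  )
  rec <- simulate_subject(cfg, plant_spec(), 1)
  expect_equal(nrow(rec$events), 2)
  expect_equal(ncol(rec$data), 2 * 100)
})

test_that("generation is bitwise deterministic under a fixed seed", {
  cfg <- eeg_protocol(
    n_subjects = 2, n_trials_per_class = 2, rest_s = 1,
    stim_s = 2, fs = 100, seed = 11,
    channel_labels = frontal_montage()
  )
  d1 <- simulate_dataset(cfg, plant_spec())
  d2 <- simulate_dataset(cfg, plant_spec())
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$recordings[[1]]$data, d2$recordings[[1]]$data)
  expect_identical(d1$recordings[[2]]$data, d2$recordings[[2]]$data)
})

test_that("manifest pools subjects x trials", {
  cfg <- eeg_protocol(
    n_subjects = 3, n_trials_per_class = 2, rest_s = 1,
    stim_s = 2, fs = 100, seed = 5, channel_labels = frontal_montage()
  )
  ds <- simulate_dataset(cfg, plant_spec())
  expect_equal(length(ds$recordings), 3)
  expect_equal(nrow(ds$manifest), 3 * 4)
  expect_equal(sort(unique(ds$manifest$subject)), 1:3)
})

test_that("planted pair coherence is recovered on a long realization", {
  cfg <- eeg_protocol(
    n_subjects = 1, n_trials_per_class = 1, rest_s = 1,
    stim_s = 200, fs = 128, seed = 42, channel_labels = frontal_montage()
  )
  pl <- plant_spec(coherent_pairs = tibble::tibble(
    ch_a = "Fp1", ch_b = "Fp2", hva = 0.8, lva = 0.8
  ))
  rec <- simulate_subject(cfg, pl, 1)
  on <- rec$events$onset[1]
  idx <- on:(on + 200 * cfg$fs - 1)
  est <- coherence_pair(rec$data["Fp1", idx], rec$data["Fp2", idx],
    fs = cfg$fs
  )
  expect_lt(abs(est - 0.8), 0.05)
})

test_that("channels outside coherent pairs sit at the independence floor", {
  cfg <- eeg_protocol(
    n_subjects = 1, n_trials_per_class = 1, rest_s = 1,
    stim_s = 60, fs = 128, seed = 7, channel_labels = frontal_montage()
  )
  pl <- plant_spec(coherent_pairs = tibble::tibble(
    ch_a = "Fp1", ch_b = "Fp2", hva = 0.6, lva = 0.6
  ))
  rec <- simulate_subject(cfg, pl, 1)
  on <- rec$events$onset[1]
  idx <- on:(on + 60 * cfg$fs - 1)
  # K ~ 119 segments -> bias floor ~ sqrt(pi/(4K)) ~ 0.08
  est <- coherence_pair(rec$data["F3", idx], rec$data["F4", idx],
    fs = cfg$fs
  )
  expect_lt(est, 0.2)
  est2 <- coherence_pair(rec$data["Fp1", idx], rec$data["F8", idx],
    fs = cfg$fs
  )
  expect_lt(est2, 0.2)
})

test_that("class power contrast lands on discriminative channels only", {
  cfg <- eeg_protocol(
    n_subjects = 5, n_trials_per_class = 5, rest_s = 1,
    stim_s = 4, fs = 128, seed = 13, channel_labels = frontal_montage()
  )
  pl <- plant_spec(
    discriminative_channels = c("Fp1", "F7"), amplitude_effect = 3,
    coherent_pairs = empty_pairs()
  )
  band_power <- function(x, fs) {
    sp <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    mean(sp[f >= 8 & f <= 30])
  }
  pow <- list(HVA = list(), LVA = list())
  for (s in 1:5) {
    rec <- simulate_subject(cfg, pl, s)
    for (i in seq_len(nrow(rec$events))) {
      on <- rec$events$onset[i]
      idx <- on:(on + 4 * cfg$fs - 1)
      lab <- rec$events$label[i]
      pow[[lab]][[length(pow[[lab]]) + 1]] <- c(
        disc = band_power(rec$data["Fp1", idx], cfg$fs),
        ref = band_power(rec$data["Fz", idx], cfg$fs)
      )
    }
  }
  hva <- do.call(rbind, pow$HVA)
  lva <- do.call(rbind, pow$LVA)
  # 25 trials per class: the planted channel separates at alpha = 0.01,
  # the reference channel does not
  expect_lt(t.test(hva[, "disc"], lva[, "disc"])$p.value, 0.01)
  expect_gt(t.test(hva[, "ref"], lva[, "ref"])$p.value, 0.01)
  expect_gt(mean(hva[, "disc"]) / mean(lva[, "disc"]), 1.5)
})

test_that("invalid plant configurations are rejected", {
  cfg <- eeg_protocol(channel_labels = frontal_montage())
  expect_error(
    validate_plant <- simulate_subject(
      cfg, plant_spec(discriminative_channels = "Oz"), 1
    ),
    class = "emofc_config_error"
  )
  expect_error(
    plant_spec(coherent_pairs = tibble::tibble(
      ch_a = "Fp1", ch_b = "Fp2", hva = 1.2, lva = 0.3
    )),
    class = "emofc_config_error"
  )
  expect_error(eeg_protocol(fs = 50), class = "emofc_config_error")
  expect_error(
    eeg_protocol(channel_labels = c("Fp1", "Fp1")),
    class = "emofc_config_error"
  )
})

test_that("the optional ocular artifact is frontal and removable", {
  cfg <- eeg_protocol(
    n_subjects = 1, n_trials_per_class = 1, rest_s = 1,
    stim_s = 10, fs = 128, seed = 9, channel_labels = frontal_montage()
  )
  rec <- simulate_subject(cfg, plant_spec(eog_artifact = TRUE), 1)
  expect_false(is.null(rec$artifact))
  r_before <- abs(cor(rec$data["Fp1", ], rec$artifact))
  cleaned <- remove_artifact(rec)
  r_after <- abs(cor(cleaned$data["Fp1", ], rec$artifact))
  expect_gt(r_before, 0.5)
  expect_lt(r_after, 1e-6)
})
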