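# Synthetic EEG generation.
#
# Generative model: each channel is Gaussian noise with a 1/f^alpha
# background spectrum plus band-limited oscillatory bumps (alpha/beta by
# default), synthesized in the frequency domain so the population PSD is
# known exactly. Channel pairs listed in the plant's `coherent_pairs` share
# a common band-shaped source during stimulation windows:
#   x_c = w_c * s + sqrt(1 - w_c^2) * n_c
# with s and n_c independent realizations of the *same* spectrum. The
# population magnitude coherence of two such channels is then w_a * w_b at
# every frequency, so a per-class coherence target t is planted exactly by
# solving w_a * w_b = t. The class power contrast multiplies the
# oscillatory-bump power on discriminative channels for HVA trials.

# ---- spectra -------------------------------------------------------------

# one-sided PSD function for the plant's background + oscillation model;
# `boost` scales the oscillatory bump power (the HVA amplitude effect)
spectral_density_fun <- function(plant, boost = 1) {
  alpha <- plant$noise_exponent
  bands <- plant$osc_bands
  function(f) {
    base <- pmax(f, 1)^(-alpha)
    # soft rolloff above 45 Hz: content is band-limited like filtered EEG
    base <- base * ifelse(f > 45, exp(-(f - 45) / 2), 1)
    s <- base
    if (nrow(bands) > 0) {
      for (i in seq_len(nrow(bands))) {
        lo <- bands$low[i]
        hi <- bands$high[i]
        dens <- bands$rel_power[i] * pmax(lo, 1)^(-alpha) * boost
        # raised-cosine edges over 1 Hz on each side
        w <- rep(0, length(f))
        w[f >= lo & f <= hi] <- 1
        ramp_lo <- f >= lo - 1 & f < lo
        w[ramp_lo] <- 0.5 * (1 + cos(pi * (lo - f[ramp_lo])))
        ramp_hi <- f > hi & f <= hi + 1
        w[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - hi)))
        s <- s + dens * w
      }
    }
    s[f <= 0] <- 0
    s
  }
}

# Gaussian noise of length n with one-sided PSD S(f); mean zero.
# Frequency-domain synthesis: sigma_k^2 = S(f_k) * n * fs / 2 gives
# var(x) = sum S(f_k) * fs / n ~= integral of S, independent of n.
colored_noise <- function(n, fs, Sfun) {
  nyq <- n %/% 2
  k <- seq_len(nyq - 1)
  f <- k * fs / n
  sig <- sqrt(Sfun(f) * n * fs / 2)
  X <- complex(
    real = rnorm(nyq - 1) * sig / sqrt(2),
    imaginary = rnorm(nyq - 1) * sig / sqrt(2)
  )
  if (n %% 2 == 0) {
    fn <- nyq * fs / n
    Xn <- rnorm(1) * sqrt(Sfun(fn) * n * fs / 2)
    spec <- c(0, X, Xn, Conj(rev(X)))
  } else {
    spec <- c(0, X, Conj(rev(X)))
  }
  Re(fft(spec, inverse = TRUE)) / n
}

# population variance of colored_noise(n, fs, Sfun)
expected_variance <- function(n, fs, Sfun) {
  nyq <- n %/% 2
  k <- seq_len(if (n %% 2 == 0) nyq else nyq)
  f <- k * fs / n
  sum(Sfun(f)) * fs / n
}

# ---- coherence plant: mixing weights ------------------------------------

# connected components of the coherent-pair graph (tiny; union-find)
pair_components <- function(pairs) {
  labs <- unique(c(pairs$ch_a, pairs$ch_b))
  parent <- setNames(labs, labs)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs$ch_a[i])
    rb <- find(pairs$ch_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(labs, find, character(1))
  split(labs, roots)
}

# solve per-channel mixing weights so that w_a * w_b hits each pair's
# target; least squares in log-weights (exact when targets are consistent,
# minimum-norm when under-determined)
solve_mix_weights <- function(members, pairs, targets) {
  if (nrow(pairs) == 1) {
    w <- sqrt(targets)
    return(setNames(rep(w, 2), c(pairs$ch_a, pairs$ch_b)))
  }
  m <- matrix(0, nrow(pairs), length(members),
    dimnames = list(NULL, members)
  )
  for (i in seq_len(nrow(pairs))) {
    m[i, pairs$ch_a[i]] <- 1
    m[i, pairs$ch_b[i]] <- 1
  }
  b <- log(pmax(targets, 1e-8))
  sv <- svd(m)
  keep <- sv$d > 1e-10 * sv$d[1]
  x <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  w <- exp(drop(x))
  setNames(pmin(w, 0.9999), members)
}

# per-class mixing plan: list of groups, each with members and weights
mixing_plan <- function(plant) {
  pairs <- plant$coherent_pairs
  if (nrow(pairs) == 0) {
    return(list())
  }
  comps <- pair_components(pairs)
  lapply(comps, function(members) {
    sel <- pairs$ch_a %in% members | pairs$ch_b %in% members
    p <- pairs[sel, , drop = FALSE]
    list(
      members = members,
      w_hva = solve_mix_weights(members, p, p$hva),
      w_lva = solve_mix_weights(members, p, p$lva)
    )
  })
}

# ---- recording container -------------------------------------------------

#' Construct an EEG recording object
#'
#' A continuous multichannel recording: a channels x samples matrix in
#' microvolts with montage labels, sampling rate and stimulation event
#' markers.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate, Hz.
#' @param labels Character vector of channel labels (one per row).
#' @param events Tibble with columns `onset` (1-based sample of stimulation
#'   onset), `trial`, `class_trial`, `label` (`"HVA"`/`"LVA"`).
#' @param subject_id Integer subject identifier.
#' @param artifact Optional numeric vector, a recorded artifact reference
#'   (e.g. ocular) of the same length as the data.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels, events, subject_id = NA_integer_,
                          artifact = NULL) {
  if (nrow(data) != length(labels)) {
    abort_emofc("`labels` length must equal the data row count",
      class = "emofc_config_error"
    )
  }
  events <- tibble::as_tibble(events)
  if (nrow(events) > 0 &&
    (any(events$onset < 1) || any(events$onset > ncol(data)))) {
    abort_emofc("event onsets out of bounds", class = "emofc_config_error")
  }
  structure(
    list(
      data = data, fs = fs, labels = as.character(labels),
      events = events, subject_id = subject_id, artifact = artifact
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s: %d ch x %d samples (%.1f s @ %g Hz), %d events\n",
    x$subject_id, nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs,
    nrow(x$events)
  ))
  invisible(x)
}

#' Convert a recording to a long tibble
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return Tibble with columns `channel`, `time`, `value`.
#' @method as_tibble eeg_recording
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$labels, each = ncol(x$data)),
    time = rep(seq_len(ncol(x$data)) / x$fs, times = nrow(x$data)),
    value = as.vector(t(x$data))
  )
}

# ---- generation ----------------------------------------------------------

#' Simulate one subject's continuous EEG recording
#'
#' Generates a continuous recording following the protocol (alternating
#' rest / stimulation / rest trials, randomized class order) with the
#' plant's class structure embedded in the stimulation windows. Pairwise
#' population coherence of planted pairs equals the class target during
#' stimulation; all other channel pairs are independent.
#'
#' @param cfg An [eeg_protocol()].
#' @param plant A [plant_spec()].
#' @param subject_id Integer; also seeds this subject's random stream
#'   (derived from `cfg$seed`, so a fixed protocol seed fixes every
#'   sample).
#' @return An [eeg_recording()] with one stimulation event per trial.
#' @export
#' @examples
#' cfg <- eeg_protocol(n_subjects = 1, n_trials_per_class = 1, fs = 100)
#' rec <- simulate_subject(cfg, plant_spec(), subject_id = 1)
#' rec
simulate_subject <- function(cfg, plant = plant_spec(), subject_id = 1L) {
  validate_plant(plant, cfg)
  with_seed(derive_seed(cfg$seed, subject_id), {
    fs <- cfg$fs
    labels <- cfg$channel_labels
    n_ch <- length(labels)
    n_trials <- 2L * cfg$n_trials_per_class
    trial_len <- round((2 * cfg$rest_s + cfg$stim_s) * fs)
    stim_len <- round(cfg$stim_s * fs)
    rest_len <- round(cfg$rest_s * fs)
    n_total <- n_trials * trial_len

    s_base <- spectral_density_fun(plant, boost = 1)
    s_boost <- spectral_density_fun(plant, boost = plant$amplitude_effect)
    scale_uv <- plant$channel_sd /
      sqrt(expected_variance(max(stim_len, 256), fs, s_base))

    # class order: randomized permutation of 6 HVA + 6 LVA
    seq_labels <- sample(rep(
      c("HVA", "LVA"),
      each = cfg$n_trials_per_class
    ))
    onsets <- (seq_len(n_trials) - 1L) * trial_len + rest_len + 1L

    # continuous background per channel
    data <- matrix(0, n_ch, n_total, dimnames = list(labels, NULL))
    for (c in seq_len(n_ch)) {
      data[c, ] <- colored_noise(n_total, fs, s_base)
    }

    plan <- mixing_plan(plant)
    grouped <- unlist(lapply(plan, `[[`, "members"))
    disc <- plant$discriminative_channels

    for (tr in seq_len(n_trials)) {
      idx <- onsets[tr]:(onsets[tr] + stim_len - 1L)
      hva <- seq_labels[tr] == "HVA"
      # independent discriminative channels: regenerate boosted content
      if (hva && plant$amplitude_effect != 1) {
        for (ch in setdiff(disc, grouped)) {
          data[ch, idx] <- colored_noise(stim_len, fs, s_boost)
        }
      }
      # coherent groups: shared source + idiosyncratic noise
      for (g in plan) {
        boosted <- hva && all(g$members %in% disc) &&
          plant$amplitude_effect != 1
        sfun <- if (boosted) s_boost else s_base
        w <- if (hva) g$w_hva else g$w_lva
        src <- colored_noise(stim_len, fs, sfun)
        for (ch in g$members) {
          data[ch, idx] <- w[[ch]] * src +
            sqrt(1 - w[[ch]]^2) * colored_noise(stim_len, fs, sfun)
        }
      }
    }

    data <- data * scale_uv

    artifact <- NULL
    if (plant$eog_artifact) {
      # slow (0.3-3 Hz) high-amplitude frontal component, blink-like
      eog_s <- function(f) ifelse(f >= 0.3 & f <= 3, 1, 0)
      artifact <- colored_noise(n_total, fs, eog_s)
      artifact <- artifact / sd(artifact) * 30
      gains <- c(Fp1 = 1, Fpz = 1, Fp2 = 1, F7 = 0.5, F8 = 0.5,
                 F3 = 0.3, Fz = 0.3, F4 = 0.3)
      for (ch in intersect(names(gains), labels)) {
        data[ch, ] <- data[ch, ] + gains[[ch]] * artifact
      }
    }

    events <- tibble::tibble(
      onset = onsets,
      trial = seq_len(n_trials),
      class_trial = stats::ave(seq_len(n_trials), seq_labels,
        FUN = seq_along
      ),
      label = seq_labels
    )
    eeg_recording(data, fs, labels, events,
      subject_id = as.integer(subject_id), artifact = artifact
    )
  })
}

#' Simulate a full multi-subject dataset
#'
#' One continuous recording per subject plus a trial manifest. Fully
#' deterministic under the protocol seed: calling twice with the same
#' configuration gives identical samples and manifests.
#'
#' @param cfg An [eeg_protocol()].
#' @param plant A [plant_spec()].
#' @return List of class `eeg_dataset`: `recordings` (list of
#'   [eeg_recording()]) and `manifest` (tibble with one row per
#'   stimulation trial: subject, trial, class_trial, label, onset).
#' @export
simulate_dataset <- function(cfg, plant = plant_spec()) {
  recordings <- lapply(
    seq_len(cfg$n_subjects),
    function(s) simulate_subject(cfg, plant, subject_id = s)
  )
  manifest <- purrr::map_dfr(recordings, function(rec) {
    dplyr::mutate(rec$events, subject = rec$subject_id, .before = 1)
  })
  structure(
    list(recordings = recordings, manifest = manifest, cfg = cfg,
         plant = plant),
    class = "eeg_dataset"
  )
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf(
    "<eeg_dataset> %d subjects, %d trials total (%d HVA / %d LVA)\n",
    length(x$recordings), nrow(x$manifest),
    sum(x$manifest$label == "HVA"), sum(x$manifest$label == "LVA")
  ))
  invisible(x)
}
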