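# Magnitude coherence functional connectivity.
#
# Estimator: Welch-style segment averaging. Within a trial, each channel
# is cut into Hann-tapered segments (default 1 s, 50% overlap; 39
# segments in a 20-s trial); writing the k-th segment spectrum as
# A(f,k) e^{i phi(f,k)}, the coherence of channels x and y is
#
#   Coh_xy(f) = | (1/n) sum_k Ax Ay e^{i(phi_x - phi_y)} |
#               / sqrt( (1/n sum_k Ax^2) (1/n sum_k Ay^2) )
#
# i.e. |averaged cross-spectrum| normalized by the averaged auto-spectra
# (magnitude, not squared), then averaged over the analysis band
# (default 1-40 Hz) to a single scalar per pair.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

# Hann-tapered, mean-removed segment spectra of one signal.
# Returns the one-sided complex spectra (n_freq x n_segments) and the
# frequency grid.
spectral_segments <- function(x, fs, seg_len_s = 1, overlap = 0.5) {
  len <- round(seg_len_s * fs)
  if (len < 4 || len > length(x)) {
    abort_emofc("segment length unusable for this signal",
      class = "emofc_config_error"
    )
  }
  step <- max(1L, round(len * (1 - overlap)))
  starts <- seq(1L, length(x) - len + 1L, by = step)
  if (length(starts) < 2) {
    abort_emofc(
      "fewer than 2 segments: single-segment coherence is identically 1",
      class = "emofc_config_error"
    )
  }
  w <- hann_window(len)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + len - 1L)]
    (seg - mean(seg)) * w
  }, numeric(len))
  nf <- len %/% 2 + 1L
  list(
    Z = stats::mvfft(segs)[seq_len(nf), , drop = FALSE],
    f = (seq_len(nf) - 1L) * fs / len
  )
}

coherence_from_spectra <- function(zx, zy) {
  num <- Mod(rowMeans(zx * Conj(zy)))
  den <- sqrt(rowMeans(Mod(zx)^2) * rowMeans(Mod(zy)^2))
  coh <- ifelse(den > 0, num / den, 0)
  pmin(coh, 1)
}

#' Band-averaged magnitude coherence of two signals
#'
#' Estimates the per-frequency magnitude coherence by Welch segment
#' averaging (Hann taper) and averages it over the analysis band. The
#' result lies in \[0, 1\]: 1 for identical (or amplitude-scaled)
#' signals, near the estimator's bias floor (about `sqrt(pi / (4 K))`
#' for K segments) for independent signals.
#'
#' @param x,y Numeric signals of equal length.
#' @param fs Sampling rate, Hz.
#' @param seg_len_s Segment length in seconds (default 1).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param band Frequency band in Hz to average over (default `c(1, 40)`).
#' @return Scalar coherence in \[0, 1\].
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1 / 100))
#' coherence_pair(x, x, fs = 100) # exactly 1
coherence_pair <- function(x, y, fs, seg_len_s = 1, overlap = 0.5,
                           band = c(1, 40)) {
  if (length(x) != length(y)) {
    abort_emofc("signals must have equal length",
      class = "emofc_config_error"
    )
  }
  sx <- spectral_segments(x, fs, seg_len_s, overlap)
  sy <- spectral_segments(y, fs, seg_len_s, overlap)
  coh <- coherence_from_spectra(sx$Z, sy$Z)
  sel <- sx$f >= band[1] & sx$f <= band[2]
  mean(coh[sel])
}

#' Per-trial functional-connectivity matrix
#'
#' Band-averaged magnitude coherence between every unordered pair of the
#' requested channels within one stimulation epoch. Symmetric by
#' construction with unit diagonal.
#'
#' @param segment Channels x samples matrix with channel row names (one
#'   trial's stimulation window).
#' @param channels Channel labels to include (default: frontal subset).
#' @param fs Sampling rate, Hz.
#' @inheritParams coherence_pair
#' @return A `coherence_matrix`: square numeric matrix in \[0, 1\] with
#'   dimnames, attribute `band`.
#' @export
trial_fc_matrix <- function(segment, channels = frontal_subset(), fs,
                            seg_len_s = 1, overlap = 0.5, band = c(1, 40)) {
  missing <- setdiff(channels, rownames(segment))
  if (length(missing) > 0) {
    abort_emofc(sprintf("channel(s) missing from segment: %s",
      paste(missing, collapse = ", ")), class = "emofc_config_error")
  }
  specs <- lapply(channels, function(ch) {
    spectral_segments(segment[ch, ], fs, seg_len_s, overlap)
  })
  sel <- specs[[1]]$f >= band[1] & specs[[1]]$f <= band[2]
  n <- length(channels)
  m <- diag(1, n)
  dimnames(m) <- list(channels, channels)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        coh <- coherence_from_spectra(specs[[i]]$Z, specs[[j]]$Z)
        m[i, j] <- m[j, i] <- mean(coh[sel])
      }
    }
  }
  structure(m, class = c("coherence_matrix", "matrix", "array"),
    band = band)
}

#' Functional connectivity for every trial of a segments tibble
#'
#' @param segments Tibble from [segment_trials()] /
#'   [preprocess_recording()] (list-column `data`).
#' @param channels Channels to include (default frontal subset).
#' @param fs Sampling rate, Hz.
#' @inheritParams coherence_pair
#' @return The tibble with a list-column `fc` of `coherence_matrix`
#'   objects (columns `data`/`baseline` dropped).
#' @export
fc_dataset <- function(segments, channels = frontal_subset(), fs,
                       seg_len_s = 1, overlap = 0.5, band = c(1, 40)) {
  fc <- purrr::map(segments$data, trial_fc_matrix,
    channels = channels,
    fs = fs, seg_len_s = seg_len_s, overlap = overlap, band = band
  )
  out <- dplyr::select(segments, -dplyr::any_of(c("data", "baseline")))
  out$fc <- fc
  out
}

#' Long-format coherence table
#'
#' @param x A `coherence_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `ch_a`, `ch_b`, `coherence` (upper
#'   triangle only).
#' @method tidy coherence_matrix
#' @export
tidy.coherence_matrix <- function(x, ...) {
  labs <- rownames(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    ch_a = labs[ut[, 1]], ch_b = labs[ut[, 2]],
    coherence = x[ut]
  )
}

#' Dynamic (trial-concatenated) connectivity features
#'
#' For each subject and class, concatenates that class's first `k`
#' per-trial coherence matrices in chronological order and encodes the
#' concatenation as one image ([encode_fc_image()]); with 8 channels and
#' k = 6 the pre-encoding shape is 8 x 48. Subjects with fewer than `k`
#' trials of a class are skipped with a warning.
#'
#' @param fc Tibble from [fc_dataset()] (columns `subject`, `label`,
#'   `class_trial`, list-column `fc`).
#' @param k Number of trials to concatenate (1-6 under the default
#'   protocol).
#' @return Tibble with columns `subject`, `label`, `k` and list-column
#'   `image`.
#' @export
dynamic_fc_features <- function(fc, k = 1) {
  stopifnot_scalar_count(k, "k")
  groups <- dplyr::group_split(dplyr::group_by(fc, .data$subject,
    .data$label))
  rows <- purrr::map(groups, function(g) {
    g <- dplyr::arrange(g, .data$class_trial)
    if (nrow(g) < k) {
      warning(sprintf("subject %s has %d < %d %s trials: skipped",
        g$subject[1], nrow(g), k, g$label[1]), call. = FALSE)
      return(NULL)
    }
    tibble::tibble(
      subject = g$subject[1], label = g$label[1], k = k,
      image = list(encode_fc_image(g$fc[seq_len(k)]))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort_emofc("no subject has enough trials", class = "emofc_config_error")
  }
  out
}

#' Compare mean functional connectivity between emotion states
#'
#' For each subject and state, Fisher r-to-z transforms every
#' upper-triangle coherence (z = atanh(coh)), averages z over pairs and
#' trials, and compares the two states across subjects with a paired
#' t-test. Coherence values at 1 are clipped to `1 - 1e-12` with a
#' warning (infinite z otherwise).
#'
#' @param fc Tibble from [fc_dataset()].
#' @return Object of class `fc_comparison`: per-subject state means,
#'   per-state mean +/- SD (z scale and back-transformed), paired t
#'   statistic and p value.
#' @export
compare_fc_states <- function(fc) {
  mean_z <- function(mats) {
    vals <- unlist(lapply(mats, function(m) m[upper.tri(m)]))
    if (any(vals >= 1)) {
      warning("coherence at 1 clipped before Fisher z", call. = FALSE)
      vals <- pmin(vals, 1 - 1e-12)
    }
    mean(atanh(vals))
  }
  per <- dplyr::summarise(
    dplyr::group_by(fc, .data$subject, .data$label),
    z = mean_z(.data$fc), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(per, names_from = "label", values_from = "z")
  if (!all(c("HVA", "LVA") %in% names(wide)) ||
    anyNA(wide[c("HVA", "LVA")])) {
    abort_emofc("both states are required for every subject",
      class = "emofc_config_error"
    )
  }
  diffs <- wide$LVA - wide$HVA
  if (sd(diffs) == 0 || length(diffs) < 2) {
    # degenerate paired design (identical states): no evidence either way
    tt <- list(
      statistic = c(t = 0), parameter = c(df = length(diffs) - 1),
      p.value = 1
    )
  } else {
    tt <- t.test(wide$LVA, wide$HVA, paired = TRUE)
  }
  structure(
    list(
      subject_means = wide,
      summary = tibble::tibble(
        state = c("HVA", "LVA"),
        mean_z = c(mean(wide$HVA), mean(wide$LVA)),
        sd_z = c(sd(wide$HVA), sd(wide$LVA)),
        mean_coherence = tanh(c(mean(wide$HVA), mean(wide$LVA)))
      ),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value
    ),
    class = "fc_comparison"
  )
}

#' @export
print.fc_comparison <- function(x, ...) {
  cat("<fc_comparison> paired t-test on subject mean Fisher-z coherence\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %s: mean FC %.3f (z %.3f +/- %.3f)\n", s$state[i],
      s$mean_coherence[i], s$mean_z[i], s$sd_z[i]
    ))
  }
  cat(sprintf("  t(%g) = %.3f, p = %.4g\n", x$df, x$t, x$p))
  invisible(x)
}

#' @describeIn compare_fc_states Per-subject state means.
#' @param x An `fc_comparison`.
#' @param ... Unused.
#' @method tidy fc_comparison
#' @export
tidy.fc_comparison <- function(x, ...) x$subject_means

#' @describeIn compare_fc_states One-row test summary.
#' @method glance fc_comparison
#' @export
glance.fc_comparison <- function(x, ...) {
  tibble::tibble(
    hva_mean_fc = x$summary$mean_coherence[x$summary$state == "HVA"],
    lva_mean_fc = x$summary$mean_coherence[x$summary$state == "LVA"],
    t = x$t, df = x$df, p = x$p
  )
}

#' Classification performance of dynamic connectivity features
#'
#' Builds the trial-concatenated connectivity feature for each k in
#' `ks`, cross-validates the chosen classifier on it, and reports
#' per-k metrics — the "accuracy grows with concatenated trials" curve.
#'
#' @param fc Tibble from [fc_dataset()].
#' @param ks Integer vector of concatenation depths (default 1:6).
#' @param model,k_folds,seed,cfg Passed to [cross_validate()].
#' @return Tibble of class `fc_curve`: one row per k with mean/SD
#'   metrics across folds.
#' @export
dynamic_classification_curve <- function(fc, ks = 1:6, model = "mini",
                                         k_folds = 5, seed = 1L,
                                         cfg = NULL) {
  rows <- lapply(ks, function(kk) {
    feats <- dynamic_fc_features(fc, k = kk)
    cv <- cross_validate(feats,
      model = model, k = k_folds,
      seed = seed, cfg = cfg
    )
    dplyr::mutate(glance(cv), trials = kk, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fc_curve", class(out))
  out
}
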