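#' Experimental protocol configuration
#'
#' Describes the music-evoked emotion paradigm the simulator emulates: each
#' subject hears 12 music clips (6 per emotion class), every trial being a
#' 5-s rest, a 20-s stimulation, and a 5-s rest, recorded on a 32-channel
#' 10-20 montage at 500 Hz.
#'
#' @param n_subjects Number of subjects (default 15).
#' @param n_trials_per_class Stimulation trials per emotion class per
#'   subject (default 6; total trials per subject is twice this).
#' @param rest_s Rest duration before and after each stimulation, seconds
#'   (default 5).
#' @param stim_s Stimulation duration, seconds (default 20).
#' @param fs Sampling rate in Hz (default 500). Must exceed 80 Hz so the
#'   1-40 Hz analysis band sits below Nyquist.
#' @param channel_labels Ordered montage labels (default [montage_32()]).
#' @param seed Integer base seed for the simulator.
#' @return An object of class `eeg_protocol` (a named list).
#' @export
#' @examples
#' eeg_protocol()
eeg_protocol <- function(n_subjects = 15,
                         n_trials_per_class = 6,
                         rest_s = 5,
                         stim_s = 20,
                         fs = 500,
                         channel_labels = montage_32(),
                         seed = 1L) {
  stopifnot_scalar_count(n_subjects, "n_subjects")
  stopifnot_scalar_count(n_trials_per_class, "n_trials_per_class")
  if (!is.numeric(rest_s) || rest_s < 0) {
    abort_emofc("`rest_s` must be >= 0", class = "emofc_config_error")
  }
  if (!is.numeric(stim_s) || stim_s <= 0) {
    abort_emofc("`stim_s` must be > 0", class = "emofc_config_error")
  }
  if (!is.numeric(fs) || fs <= 80) {
    abort_emofc("`fs` must exceed 80 Hz (Nyquist above the 40 Hz band)",
      class = "emofc_config_error"
    )
  }
  if (anyDuplicated(channel_labels) > 0) {
    abort_emofc("`channel_labels` must be unique",
      class = "emofc_config_error"
    )
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_trials_per_class = as.integer(n_trials_per_class),
      rest_s = rest_s,
      stim_s = stim_s,
      fs = fs,
      channel_labels = as.character(channel_labels),
      seed = as.integer(seed)
    ),
    class = "eeg_protocol"
  )
}

#' @export
print.eeg_protocol <- function(x, ...) {
  cat("<eeg_protocol>\n")
  cat(sprintf(
    "  %d subjects, %d trials/class (%d total/subject)\n",
    x$n_subjects, x$n_trials_per_class, 2L * x$n_trials_per_class
  ))
  cat(sprintf(
    "  trial: %gs rest | %gs stimulation | %gs rest @ %g Hz\n",
    x$rest_s, x$stim_s, x$rest_s, x$fs
  ))
  cat(sprintf(
    "  %d channels (%s...)\n", length(x$channel_labels),
    paste(head(x$channel_labels, 6), collapse = ", ")
  ))
  invisible(x)
}

#' Planted class structure for the synthetic EEG generator
#'
#' Declares which statistical structure the generator embeds into the
#' recordings so that every downstream stage has signal to find:
#' \itemize{
#'   \item an oscillatory-power contrast between classes, confined to
#'     `discriminative_channels` (HVA trials multiply band power on those
#'     channels by `amplitude_effect`), which the image classifier and the
#'     channel search can exploit;
#'   \item pairwise magnitude coherence planted on `coherent_pairs` with a
#'     class-dependent target (default: prefrontal pairs more coherent
#'     under LVA than HVA), which the connectivity analysis recovers.
#' }
#'
#' @param discriminative_channels Channels carrying the class power
#'   contrast (default the 8 frontal channels).
#' @param amplitude_effect Multiplicative band-power contrast for HVA
#'   trials on discriminative channels (default 1.5; 1 = no contrast).
#' @param coherent_pairs Tibble with columns `ch_a`, `ch_b`, `hva`, `lva`:
#'   per-pair population coherence targets in [0, 1] for each class.
#'   Default: the three prefrontal pairs at 0.25 (HVA) vs 0.30 (LVA).
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background
#'   (default 1).
#' @param osc_bands Tibble with columns `low`, `high`, `rel_power`:
#'   band-limited oscillations added on top of the background, with power
#'   density relative to the background density at the band's low edge.
#'   Default: alpha 8-12 Hz (1.0) and beta 13-30 Hz (0.5).
#' @param eog_artifact Logical; add a low-frequency ocular-like frontal
#'   artifact (off by default) to exercise the optional artifact-removal
#'   stage.
#' @param channel_sd Per-channel signal standard deviation in microvolts
#'   under the base (LVA, non-boosted) spectrum (default 10).
#' @return An object of class `plant_spec`.
#' @export
#' @examples
#' plant_spec()
plant_spec <- function(discriminative_channels = frontal_subset(),
                       amplitude_effect = 1.5,
                       coherent_pairs = default_coherent_pairs(),
                       noise_exponent = 1,
                       osc_bands = default_osc_bands(),
                       eog_artifact = FALSE,
                       channel_sd = 10) {
  coherent_pairs <- tibble::as_tibble(coherent_pairs)
  needed <- c("ch_a", "ch_b", "hva", "lva")
  if (!all(needed %in% names(coherent_pairs))) {
    abort_emofc("`coherent_pairs` needs columns ch_a, ch_b, hva, lva",
      class = "emofc_config_error"
    )
  }
  targets <- c(coherent_pairs$hva, coherent_pairs$lva)
  if (length(targets) > 0 && (any(targets < 0) || any(targets >= 1))) {
    abort_emofc("coherence targets must lie in [0, 1)",
      class = "emofc_config_error"
    )
  }
  if (!is.numeric(amplitude_effect) || amplitude_effect <= 0) {
    abort_emofc("`amplitude_effect` must be > 0",
      class = "emofc_config_error"
    )
  }
  structure(
    list(
      discriminative_channels = as.character(discriminative_channels),
      amplitude_effect = amplitude_effect,
      coherent_pairs = coherent_pairs,
      noise_exponent = noise_exponent,
      osc_bands = tibble::as_tibble(osc_bands),
      eog_artifact = isTRUE(eog_artifact),
      channel_sd = channel_sd
    ),
    class = "plant_spec"
  )
}

#' @rdname plant_spec
#' @export
default_coherent_pairs <- function() {
  pf <- prefrontal_channels()
  tibble::tibble(
    ch_a = c(pf[1], pf[1], pf[2]),
    ch_b = c(pf[2], pf[3], pf[3]),
    hva = 0.25,
    lva = 0.30
  )
}

#' @rdname plant_spec
#' @export
default_osc_bands <- function() {
  tibble::tibble(
    low = c(8, 13),
    high = c(12, 30),
    rel_power = c(1, 0.5)
  )
}

# check a plant spec against a protocol's montage
validate_plant <- function(plant, cfg) {
  labels <- cfg$channel_labels
  bad <- setdiff(plant$discriminative_channels, labels)
  if (length(bad) > 0) {
    abort_emofc(
      sprintf(
        "discriminative channel(s) not in montage: %s",
        paste(bad, collapse = ", ")
      ),
      class = "emofc_config_error"
    )
  }
  bad <- setdiff(
    unique(c(plant$coherent_pairs$ch_a, plant$coherent_pairs$ch_b)), labels
  )
  if (length(bad) > 0) {
    abort_emofc(
      sprintf(
        "coherent pair channel(s) not in montage: %s",
        paste(bad, collapse = ", ")
      ),
      class = "emofc_config_error"
    )
  }
  invisible(TRUE)
}
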