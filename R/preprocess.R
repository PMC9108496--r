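# Preprocessing chain: notch -> bandpass -> CAR -> (optional artifact
# regression) -> segmentation with baseline correction.

# zero-phase filtering with reflection padding to suppress edge transients
filtfilt_pad <- function(b, a, x, pad = NULL) {
  n <- length(x)
  pad <- min(pad %||% max(3 * (length(a) + length(b)), 100), n - 1)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(signal::Arma(b = b, a = a), c(left, x, right))
  y[(pad + 1):(pad + n)]
}

# linear-phase FIR applied forward with delay compensation (exact
# zero-phase for symmetric h of odd length), with reflection padding
fir_zerophase <- function(h, x) {
  n <- length(x)
  m <- (length(h) - 1L) / 2L
  pad <- min(length(h), n - 1)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xx <- c(left, x, right, rep(0, m))
  y <- signal::fftfilt(h, xx)
  y[(pad + m + 1):(pad + m + n)]
}

# Hamming windowed-sinc FIR bandpass; cutoffs at -6 dB, odd tap count
design_fir_bandpass <- function(band, fs, transition = 1.8) {
  ntaps <- ceiling(3.3 / (transition / fs))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- (ntaps - 1) / 2
  t <- seq(-m, m)
  sinc <- function(fc) {
    out <- 2 * fc / fs * rep(1, length(t))
    nz <- t != 0
    out[nz] <- sin(2 * pi * fc / fs * t[nz]) / (pi * t[nz])
    out
  }
  h <- sinc(band[2]) - sinc(band[1])
  h * (0.54 + 0.46 * cos(pi * t / m))
}

apply_by_channel <- function(rec, fun) {
  out <- rec
  for (i in seq_len(nrow(rec$data))) out$data[i, ] <- fun(rec$data[i, ])
  out
}

#' Notch filter (powerline removal)
#'
#' Zero-phase Butterworth band-stop filter, by default 49-51 Hz, removing
#' 50 Hz mains interference. Power at 50 Hz is attenuated by far more than
#' 30 dB while the passband below 45 Hz is left within 1 dB.
#'
#' @param rec An [eeg_recording()].
#' @param stop_band Length-2 numeric, stop-band edges in Hz.
#' @param order Butterworth prototype order per edge (default 2; the
#'   forward-backward pass doubles the effective order).
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, stop_band = c(49, 51), order = 2) {
  if (rec$fs <= 2 * stop_band[2]) {
    abort_emofc(
      sprintf("fs = %g too low for a %g-%g Hz notch", rec$fs,
        stop_band[1], stop_band[2]),
      class = "emofc_config_error"
    )
  }
  flt <- signal::butter(order, stop_band / (rec$fs / 2), type = "stop")
  # narrow stop bands ring for ~fs/bandwidth samples: pad generously
  pad <- round(2 * rec$fs / max(diff(stop_band), 0.5))
  apply_by_channel(rec, function(x) filtfilt_pad(flt$b, flt$a, x, pad))
}

#' Bandpass filter
#'
#' Zero-phase Hamming windowed-sinc FIR bandpass, by default 1-40 Hz. The
#' linear-phase FIR is applied with its group delay compensated, so the
#' filter is exactly zero-phase; stop bands (0.1 Hz, 60 Hz) are attenuated
#' by more than 30 dB and the 2-38 Hz passband ripple is under 1 dB.
#'
#' @param rec An [eeg_recording()].
#' @param band Length-2 numeric, passband edges in Hz.
#' @param transition Transition width in Hz (default 1.8, narrow enough
#'   that 0.1 Hz falls in the lower stop band).
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, band = c(1, 40), transition = 1.8) {
  if (rec$fs <= 2 * band[2]) {
    abort_emofc(sprintf("fs = %g too low for a %g Hz upper edge", rec$fs,
      band[2]), class = "emofc_config_error")
  }
  h <- design_fir_bandpass(band, rec$fs, transition)
  if (length(h) >= ncol(rec$data)) {
    abort_emofc("recording shorter than the bandpass impulse response",
      class = "emofc_config_error"
    )
  }
  apply_by_channel(rec, function(x) fir_zerophase(h, x))
}

#' Common average reference
#'
#' Re-references every analysis channel against the instantaneous mean of
#' the analysis channels, so that at each sample the mean across analysis
#' channels is zero. Reference electrodes (M1/M2) are excluded from the
#' average and left untouched.
#'
#' @param rec An [eeg_recording()].
#' @param analysis_labels Channels entering the average (default: all
#'   channels except M1/M2).
#' @return The re-referenced recording.
#' @export
common_average_reference <- function(rec,
                                     analysis_labels =
                                       analysis_channels(rec$labels)) {
  if (length(analysis_labels) == 0) {
    abort_emofc("empty analysis channel list",
      class = "emofc_config_error"
    )
  }
  missing <- setdiff(analysis_labels, rec$labels)
  if (length(missing) > 0) {
    abort_emofc(sprintf("channel(s) not in recording: %s",
      paste(missing, collapse = ", ")), class = "emofc_config_error")
  }
  idx <- match(analysis_labels, rec$labels)
  avg <- colMeans(rec$data[idx, , drop = FALSE])
  out <- rec
  out$data[idx, ] <- sweep(rec$data[idx, , drop = FALSE], 2, avg)
  out
}

#' Regression-based artifact removal (optional stage)
#'
#' Removes the least-squares projection of every channel onto a recorded
#' artifact reference (e.g. an ocular trace). After removal, each
#' channel's correlation with the regressor is numerically zero.
#'
#' @param rec An [eeg_recording()].
#' @param reference_artifact Numeric vector of the same length as the
#'   recording; defaults to the artifact stored in the recording, if any.
#' @return The cleaned recording.
#' @export
remove_artifact <- function(rec, reference_artifact = rec$artifact) {
  if (is.null(reference_artifact)) {
    abort_emofc("no artifact reference supplied",
      class = "emofc_config_error"
    )
  }
  if (length(reference_artifact) != ncol(rec$data)) {
    abort_emofc("artifact reference length must match the recording",
      class = "emofc_config_error"
    )
  }
  a <- reference_artifact - mean(reference_artifact)
  denom <- sum(a^2)
  if (denom == 0) {
    abort_emofc("artifact reference has zero variance",
      class = "emofc_config_error"
    )
  }
  out <- rec
  beta <- (rec$data %*% a) / denom
  out$data <- rec$data - tcrossprod(drop(beta), a)
  out
}

#' Segment a recording into baseline-corrected trials
#'
#' Cuts one stimulation epoch per event marker, subtracts each channel's
#' mean over the pre-stimulus baseline window, and returns a tidy tibble
#' of trial segments. Events too close to the recording edge (no complete
#' baseline or stimulation window) are skipped with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param stim_s Stimulation window length in seconds.
#' @param baseline_s Pre-stimulus baseline length in seconds (default 5,
#'   the protocol's pre-stimulus rest).
#' @return A tibble with one row per kept trial: `subject`, `trial`,
#'   `class_trial`, `label`, and list-columns `data` (channels x samples
#'   stimulation matrix) and `baseline` (channels x samples baseline
#'   matrix), both baseline-corrected.
#' @export
segment_trials <- function(rec, stim_s = 20, baseline_s = 5) {
  fs <- rec$fs
  stim_len <- round(stim_s * fs)
  base_len <- round(baseline_s * fs)
  n <- ncol(rec$data)
  keep <- rec$events$onset - base_len >= 1 &
    rec$events$onset + stim_len - 1 <= n
  if (any(!keep)) {
    warning(sprintf("skipping %d event(s) too close to the recording edge",
      sum(!keep)), call. = FALSE)
  }
  ev <- rec$events[keep, , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(ev)), function(i) {
    on <- ev$onset[i]
    stim <- rec$data[, on:(on + stim_len - 1), drop = FALSE]
    base <- rec$data[, (on - base_len):(on - 1), drop = FALSE]
    mu <- rowMeans(base)
    tibble::tibble(
      subject = rec$subject_id,
      trial = ev$trial[i],
      class_trial = ev$class_trial[i],
      label = ev$label[i],
      data = list(stim - mu),
      baseline = list(base - mu)
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the full preprocessing chain on one recording
#'
#' Applies, in order: notch filter, bandpass filter, common average
#' reference, optional regression-based artifact removal, and trial
#' segmentation with baseline correction.
#'
#' @param rec An [eeg_recording()].
#' @param notch Stop-band edges in Hz (default `c(49, 51)`).
#' @param band Passband edges in Hz (default `c(1, 40)`).
#' @param stim_s,baseline_s Segmentation windows in seconds.
#' @param remove_eog If `TRUE` and the recording carries an artifact
#'   reference, regress it out before segmenting.
#' @param analysis_labels Channels for the common average reference.
#' @return Tibble of trial segments, as [segment_trials()].
#' @export
preprocess_recording <- function(rec, notch = c(49, 51), band = c(1, 40),
                                 stim_s = 20, baseline_s = 5,
                                 remove_eog = FALSE,
                                 analysis_labels =
                                   analysis_channels(rec$labels)) {
  rec <- notch_filter(rec, notch)
  rec <- bandpass_filter(rec, band)
  rec <- common_average_reference(rec, analysis_labels)
  if (remove_eog && !is.null(rec$artifact)) rec <- remove_artifact(rec)
  segment_trials(rec, stim_s = stim_s, baseline_s = baseline_s)
}
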