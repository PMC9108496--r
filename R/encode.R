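# EEG-to-image encoding: per-second decimated channel x time matrices,
# min-max scaled to 8-bit pixel range.

#' Per-second sample matrices from a trial segment
#'
#' Splits a stimulation epoch into 1-s windows and keeps `points_per_second`
#' uniformly spaced samples per channel from each window (plain stride
#' decimation; at 500 Hz and 20 points the stride is 25 samples). Each
#' window becomes one channels x points matrix, the unit the classifier
#' consumes.
#'
#' @param segment Channels x samples numeric matrix (one stimulation
#'   epoch) with channel row names, or a segments tibble from
#'   [segment_trials()] (then all rows are expanded and the result is a
#'   tidy tibble).
#' @param fs Sampling rate of the segment in Hz (taken per call; required
#'   for the matrix form).
#' @param points_per_second Points kept per second (default 20).
#' @return For a matrix: list of channels x points matrices, one per
#'   second. For a segments tibble: tibble with columns `subject`,
#'   `trial`, `class_trial`, `label`, `second`, and list-column `x`.
#' @export
window_per_second <- function(segment, fs, points_per_second = 20) {
  if (round(fs) %% points_per_second != 0) {
    message(sprintf(
      "fs = %g not divisible by %d points/s; using nearest-sample indexing",
      fs, points_per_second
    ))
  }
  if (is.data.frame(segment)) {
    out <- purrr::map(seq_len(nrow(segment)), function(i) {
      mats <- window_matrix(segment$data[[i]], fs, points_per_second)
      tibble::tibble(
        subject = segment$subject[i],
        trial = segment$trial[i],
        class_trial = segment$class_trial[i],
        label = segment$label[i],
        second = seq_along(mats),
        x = mats
      )
    })
    return(dplyr::bind_rows(out))
  }
  window_matrix(segment, fs, points_per_second)
}

window_matrix <- function(segment, fs, points_per_second) {
  n <- ncol(segment)
  fs_int <- round(fs)
  n_sec <- n %/% fs_int
  if (n_sec < 1) {
    abort_emofc("segment shorter than one second",
      class = "emofc_config_error"
    )
  }
  offsets <- (seq_len(points_per_second) - 1) * fs_int %/% points_per_second
  lapply(seq_len(n_sec), function(s) {
    segment[, (s - 1) * fs_int + offsets + 1, drop = FALSE]
  })
}

#' Encode a sample matrix as an 8-bit image
#'
#' Min-max scales a channels x points matrix to integer pixels in
#' \[0, 255\]: `Y = round(255 * (X - min(X)) / (max(X) - min(X)))`, with
#' rounding half away from zero. The global minimum maps to 0 and the
#' global maximum to 255, so the encoding is invariant to any positive
#' affine transform of the input. A constant matrix (zero range) encodes
#' to all zeros with a warning.
#'
#' @param x Finite numeric matrix (channels x points).
#' @return Integer matrix of the same shape, values in \[0, 255\], class
#'   `image_sample`. Use [image_planes()] for the replicated 3-plane form.
#' @export
#' @examples
#' encode_image(matrix(c(0, 2, 1, 4), 2))
encode_image <- function(x) {
  if (!all(is.finite(x))) {
    abort_emofc("sample matrix must be finite", class = "emofc_config_error")
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant sample matrix: zero dynamic range, image is all zeros",
      call. = FALSE
    )
    y <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  } else {
    y <- round_half_away(255 * (x - rng[1]) / (rng[2] - rng[1]))
    storage.mode(y) <- "integer"
  }
  structure(y, class = c("image_sample", class(y)))
}

#' Replicate an encoded image across three planes
#'
#' The classifier input is an RGB-shaped tensor; the grayscale image is
#' replicated onto three identical planes.
#'
#' @param y An `image_sample` (integer matrix).
#' @return Numeric array of dim `c(nrow, ncol, 3)`.
#' @export
image_planes <- function(y) {
  array(rep(as.numeric(y), 3), dim = c(nrow(y), ncol(y), 3))
}

#' Encode a sequence of coherence matrices as one image
#'
#' Concatenates per-trial connectivity matrices along the column axis in
#' chronological order (an n_ch x (n_ch * k) matrix for k trials), then
#' applies the same min-max pixel encoding as [encode_image()]. This is
#' the dynamic functional-connectivity feature.
#'
#' @param matrices List of square numeric matrices with identical
#'   dimensions, in chronological trial order.
#' @return An `image_sample` of shape n_ch x (n_ch * k).
#' @export
encode_fc_image <- function(matrices) {
  if (length(matrices) == 0) {
    abort_emofc("no matrices supplied", class = "emofc_config_error")
  }
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims != dims[, 1])) {
    abort_emofc("coherence matrices must share one shape",
      class = "emofc_config_error"
    )
  }
  encode_image(do.call(cbind, lapply(matrices, unclass)))
}

#' Encode every per-second sample of a windowed tibble
#'
#' @param samples Tibble from [window_per_second()] with list-column `x`.
#' @return The tibble with an added list-column `image` of
#'   `image_sample` matrices.
#' @export
encode_samples <- function(samples) {
  dplyr::mutate(samples, image = purrr::map(.data$x, encode_image))
}

# nearest-neighbour resize of a matrix (used to feed small images into
# architectures with a larger minimum input)
resize_nn <- function(x, out_h, out_w) {
  ri <- pmin(nrow(x), floor((seq_len(out_h) - 0.5) * nrow(x) / out_h) + 1)
  ci <- pmin(ncol(x), floor((seq_len(out_w) - 0.5) * ncol(x) / out_w) + 1)
  x[ri, ci, drop = FALSE]
}
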