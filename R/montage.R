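#' Standard 32-electrode 10-20 montage
#'
#' Channel labels of the 32-electrode international 10-20 montage used
#' throughout the package, in row order of the image encoding. `M1` and `M2`
#' are mastoid reference electrodes: they are generated and stored but
#' excluded from the 30 analysis channels.
#'
#' @return Character vector of 32 channel labels.
#' @export
#' @examples
#' montage_32()
montage_32 <- function() {
  c(
    "Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "M1", "T7", "C3", "Cz", "C4", "T8", "M2",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "POz", "O1", "Oz", "O2"
  )
}

#' Analysis channels of a montage
#'
#' Drops the mastoid reference electrodes `M1`/`M2`, leaving the 30 scalp
#' channels entering preprocessing and classification.
#'
#' @param labels Character vector of montage labels.
#' @return Character vector without the reference labels.
#' @export
analysis_channels <- function(labels = montage_32()) {
  setdiff(labels, c("M1", "M2"))
}

#' Frontal channel subset
#'
#' Returns the eight frontal-region channels used for region-specific
#' classification and as the starting set of the sequential backward
#' channel search: Fp1, Fpz, Fp2, F7, F3, Fz, F4, F8.
#'
#' @param montage Character vector of available channel labels.
#' @return Character vector of the 8 frontal labels, in montage order.
#' @export
#' @examples
#' frontal_subset()
frontal_subset <- function(montage = montage_32()) {
  frontal <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8")
  missing <- setdiff(frontal, montage)
  if (length(missing) > 0) {
    abort_emofc(
      sprintf(
        "montage is missing frontal channel(s): %s",
        paste(missing, collapse = ", ")
      ),
      class = "emofc_config_error"
    )
  }
  frontal[order(match(frontal, montage))]
}

#' Prefrontal channels
#'
#' The three anterior prefrontal electrodes (Fp1, Fpz, Fp2) where the
#' class-dependent coherence contrast is planted by default, mirroring the
#' observation that low valence-arousal states show stronger prefrontal
#' coupling than high valence-arousal states.
#'
#' @return Character vector of 3 labels.
#' @export
prefrontal_channels <- function() c("Fp1", "Fpz", "Fp2")
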