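# On-disk formats: a minimal EDF writer/reader for interoperability, and
# a raw array container (float64 + JSON sidecar) for exact round-trips.

pad_str <- function(s, n) {
  s <- substr(as.character(s), 1, n)
  formatC(s, width = -n, flag = " ")
}

#' Write a recording to an EDF file
#'
#' European Data Format: 16-bit samples with per-channel physical
#' scaling, 1-s data records. Event markers and the subject id are not
#' representable in plain EDF; write the sidecar/manifest
#' ([write_eeg_bin()], [write_manifest()]) alongside when they matter.
#' Quantization error is bounded by the per-channel physical range /
#' 65535.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- round(rec$fs)
  n_ch <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_str("0", 8),
    pad_str(sprintf("X X X subject_%s", rec$subject_id), 80),
    pad_str("Startdate X X X X", 80),
    pad_str("01.01.00", 8), pad_str("00.00.00", 8),
    pad_str(256 * (n_ch + 1), 8), pad_str("", 44),
    pad_str(n_rec, 8), pad_str("1", 8), pad_str(n_ch, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, n) {
    writeChar(paste(vapply(vals, pad_str, character(1), n = n),
      collapse = ""
    ), con, eos = NULL)
  }
  field(rec$labels, 16)
  field(rep("AgAgCl electrode", n_ch), 80)
  field(rep("uV", n_ch), 8)
  field(sprintf("%.6g", pmin_), 8)
  field(sprintf("%.6g", pmax_), 8)
  field(rep("-32768", n_ch), 8)
  field(rep("32767", n_ch), 8)
  field(rep("", n_ch), 80)
  field(rep(fs, n_ch), 8)
  field(rep("", n_ch), 32)
  scale <- 65535 / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    block <- data[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    dig <- round((block - pmin_) * scale) - 32768
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports the plain-EDF subset this package writes (uniform 1-s
#' records, 16-bit little-endian).
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] (without events; read the manifest for
#'   those).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)
  rd(80)
  rd(80)
  rd(8)
  rd(8)
  rd(8)
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), character(1))
  rd(80 * n_ch)
  rd(8 * n_ch)
  pmin_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  rd(80 * n_ch)
  spr <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  rd(32 * n_ch)
  fs <- spr[1] / dur
  data <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = sum(spr), size = 2,
      endian = "little")
    block <- matrix(raw, nrow = spr[1])
    phys <- (t(block) - dmin) / (dmax - dmin) * (pmax_ - pmin_) + pmin_
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- phys
  }
  rownames(data) <- labels
  eeg_recording(data, fs, labels,
    tibble::tibble(
      onset = integer(), trial = integer(),
      class_trial = integer(), label = character()
    )
  )
}

#' Write a recording to the raw array container
#'
#' Float64 little-endian samples plus a JSON sidecar carrying labels,
#' sampling rate, subject id and event markers. Exact round-trip
#' (bitwise) with [read_eeg_bin()].
#'
#' @param rec An [eeg_recording()].
#' @param path Output path for the binary payload; the sidecar is written
#'   to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_eeg_bin <- function(rec, path) {
  con <- file(path, "wb")
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(
    dims = dim(rec$data), fs = rec$fs, labels = rec$labels,
    subject_id = rec$subject_id, events = rec$events
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE,
    digits = NA
  )
  invisible(path)
}

#' @rdname write_eeg_bin
#' @export
read_eeg_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(path, "rb")
  vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  close(con)
  data <- matrix(vals, meta$dims[1], meta$dims[2])
  rownames(data) <- meta$labels
  eeg_recording(data, meta$fs, meta$labels,
    tibble::as_tibble(meta$events),
    subject_id = meta$subject_id
  )
}

#' Write / read a dataset trial manifest
#'
#' @param manifest Tibble (e.g. `simulate_dataset()$manifest`).
#' @param path CSV path.
#' @return `path` invisibly / the manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
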