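# Shared fixtures and independent oracles, all built in code.

# ---- brute-force coherence oracle ---------------------------------------
# Independent implementation of the segment-averaged magnitude coherence:
# explicit DFT sums with complex arithmetic written out, no fft(), no
# shared code with the package's estimator.
naive_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    ang <- -2 * pi * k * (0:(n - 1)) / n
    complex(
      real = sum(x * cos(ang)),
      imaginary = sum(x * sin(ang))
    )
  }, complex(1))
}

brute_coherence <- function(x, y, fs, seg_len_s = 1, overlap = 0.5,
                            band = c(1, 40)) {
  len <- round(seg_len_s * fs)
  step <- max(1, round(len * (1 - overlap)))
  starts <- seq(1, length(x) - len + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(len) - 1) / (len - 1)))
  zx <- sapply(starts, function(s) {
    seg <- x[s:(s + len - 1)]
    naive_dft((seg - mean(seg)) * w)
  })
  zy <- sapply(starts, function(s) {
    seg <- y[s:(s + len - 1)]
    naive_dft((seg - mean(seg)) * w)
  })
  nf <- len %/% 2 + 1
  f <- (seq_len(nf) - 1) * fs / len
  coh <- vapply(seq_len(nf), function(i) {
    cross <- mean(zx[i, ] * Conj(zy[i, ]))
    px <- mean(Mod(zx[i, ])^2)
    py <- mean(Mod(zy[i, ])^2)
    if (px * py == 0) 0 else min(Mod(cross) / sqrt(px * py), 1)
  }, numeric(1))
  mean(coh[f >= band[1] & f <= band[2]])
}

# ---- linearly separable image fixture -----------------------------------
# HVA images carry an additive mean offset on a fixed row block, so a
# linear classifier in pixel space separates the classes perfectly.
make_separable_samples <- function(n_per_class, seed = 1, offset = 120,
                                   noise_sd = 15) {
  set.seed(seed)
  rows <- paste0("ch", 1:8)
  mk <- function(lab) {
    m <- matrix(rnorm(8 * 20, mean = 128, sd = noise_sd), 8, 20,
      dimnames = list(rows, NULL)
    )
    # anchor pixels so the min-max scale is commensurate across images
    m[1, 1] <- 0
    m[1, 2] <- 255
    if (lab == "HVA") m[3:5, 6:15] <- m[3:5, 6:15] + offset
    encode_image(m)
  }
  labs <- rep(c("HVA", "LVA"), each = n_per_class)
  tibble::tibble(
    image = lapply(labs, mk),
    label = labs,
    subject = rep(1:2, length.out = 2 * n_per_class),
    trial = seq_along(labs)
  )
}

# verify a fixture is linearly separable with a pixel-space logistic model
linearly_separable <- function(samples) {
  x <- t(vapply(samples$image, function(m) as.numeric(m) / 255,
    numeric(length(samples$image[[1]]))
  ))
  x <- x[, apply(x, 2, sd) > 0, drop = FALSE] # drop constant pixels
  y <- as.numeric(samples$label == "HVA")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial())
  )
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  pr <- 1 / (1 + exp(-drop(cbind(1, x) %*% beta)))
  mean((pr > 0.5) == y) == 1
}

# ---- small synthetic EEG fixtures ---------------------------------------
empty_pairs <- function() {
  tibble::tibble(
    ch_a = character(), ch_b = character(),
    hva = numeric(), lva = numeric()
  )
}

frontal_montage <- function() c(frontal_subset(), "M1", "M2")

# encoded per-second samples with a single planted discriminative channel,
# raw-segmented (no CAR): the channel-search study fixture
make_search_samples <- function(seed, planted = "F7", effect = 12,
                                nsec = 6, n_subjects = 2) {
  cfg <- eeg_protocol(
    n_subjects = n_subjects, fs = 128, seed = seed
  )
  pl <- plant_spec(
    discriminative_channels = planted, amplitude_effect = effect,
    coherent_pairs = empty_pairs(),
    osc_bands = tibble::tibble(low = 8, high = 12, rel_power = 2)
  )
  ds <- simulate_dataset(cfg, pl)
  segs <- dplyr::bind_rows(lapply(ds$recordings, segment_trials))
  samples <- suppressMessages(
    encode_samples(window_per_second(segs, cfg$fs))
  )
  dplyr::filter(samples, second <= nsec)
}

search_model_config <- function() {
  model_config(epochs = 8, batch_size = 16, learning_rate = 1e-2)
}

# exhaustive-search oracle over all subsets of size >= min_size
all_channel_subsets <- function(labs, min_size = 2) {
  out <- list()
  for (m in min_size:length(labs)) {
    out <- c(out, utils::combn(labs, m, simplify = FALSE))
  }
  out
}

# memoise an evaluator so greedy + exhaustive share evaluations
cached_evaluator <- function(ev) {
  cache <- new.env(parent = emptyenv())
  function(chs) {
    key <- paste(sort(chs), collapse = "_")
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    v <- ev(chs)
    cache[[key]] <- v
    v
  }
}
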