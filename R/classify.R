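# Fivefold cross-validation, confusion counts, performance metrics and
# the SVM / random-forest baselines.

#' Assign samples to cross-validation parts
#'
#' Splits the samples of each class into `k` near-equal random parts.
#' Under the fold rotation ([fold_split()]), fold f uses part f as the
#' test set, the next part as validation and the remaining k-2 parts for
#' training, so every sample is tested exactly once across folds. With
#' 1800 samples per class and k = 5 this yields the 1080 / 360 / 360
#' per-class train / validation / test budget.
#'
#' @param labels Character/factor vector of class labels.
#' @param k Number of folds (default 5; must be at least 3 so the
#'   train/validation/test rotation is possible).
#' @param seed Integer seed for the random partition.
#' @return Tibble with columns `idx`, `label`, `part`.
#' @export
make_folds <- function(labels, k = 5, seed = 1L) {
  if (k < 3) {
    abort_emofc("k must be >= 3 (train/validation/test rotation)",
      class = "emofc_config_error"
    )
  }
  labels <- as.character(labels)
  with_seed(derive_seed(seed, 17L), {
    parts <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      sizes <- rep(length(idx) %/% k, k) +
        (seq_len(k) <= length(idx) %% k)
      parts[sample(idx)] <- rep(seq_len(k), times = sizes)
    }
    tibble::tibble(idx = seq_along(labels), label = labels, part = parts)
  })
}

#' Train / validation / test indices for one fold
#'
#' @param folds Tibble from [make_folds()].
#' @param fold Fold number in `1..k`.
#' @param k Number of folds.
#' @return List with integer vectors `train`, `val`, `test`.
#' @export
fold_split <- function(folds, fold, k = max(folds$part)) {
  test_part <- fold
  val_part <- fold %% k + 1
  list(
    train = folds$idx[!folds$part %in% c(test_part, val_part)],
    val = folds$idx[folds$part == val_part],
    test = folds$idx[folds$part == test_part]
  )
}

#' Confusion counts with HVA as the positive class
#'
#' @param truth,pred Character/factor vectors of true and predicted
#'   labels (`"HVA"`/`"LVA"`).
#' @param positive Positive class (default `"HVA"`).
#' @return One-row tibble with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = "HVA") {
  truth <- as.character(truth)
  pred <- as.character(pred)
  known <- class_levels()
  if (!all(truth %in% known) || !all(pred %in% known)) {
    abort_emofc("unknown class label", class = "emofc_config_error")
  }
  tibble::tibble(
    TP = sum(truth == positive & pred == positive),
    TN = sum(truth != positive & pred != positive),
    FP = sum(truth != positive & pred == positive),
    FN = sum(truth == positive & pred != positive)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision and F1 score as
#' percentages. A metric whose denominator is zero is reported as `NA`
#' (undefined), never as 0.
#'
#' @param counts One-row tibble or named list with `TP`, `TN`, `FP`, `FN`.
#' @return One-row tibble of percentages.
#' @export
#' @examples
#' compute_metrics(list(TP = 30, FN = 10, TN = 35, FP = 5))
compute_metrics <- function(counts) {
  tp <- counts$TP
  tn <- counts$TN
  fp <- counts$FP
  fn <- counts$FN
  if (any(c(tp, tn, fp, fn) < 0)) {
    abort_emofc("confusion counts must be non-negative",
      class = "emofc_config_error"
    )
  }
  total <- tp + tn + fp + fn
  if (total == 0) {
    abort_emofc("all confusion counts are zero",
      class = "emofc_config_error"
    )
  }
  frac <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- frac(tp, tp + fn)
  prec <- frac(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) {
    NA_real_
  } else {
    2 * sens * prec / (sens + prec)
  }
  tibble::tibble(
    accuracy = frac(tp + tn, total),
    sensitivity = sens,
    specificity = frac(tn, tn + fp),
    precision = prec,
    f1 = f1
  )
}

# flatten image list to a feature matrix for the baselines
flatten_images <- function(images) {
  t(vapply(images, function(m) as.numeric(m) / 255,
    numeric(length(images[[1]]))
  ))
}

#' Train a baseline classifier (SVM or random forest)
#'
#' Exploratory traditional baselines operating on flattened pixel
#' vectors: a radial-kernel support vector machine and a random forest.
#'
#' @param kind `"svm"` or `"rf"`.
#' @param images List of `image_sample` matrices.
#' @param y Labels.
#' @param seed Integer seed.
#' @return Object of class `emofc_baseline`.
#' @export
train_baseline <- function(kind = c("svm", "rf"), images, y, seed = 1L) {
  kind <- match.arg(kind)
  if (length(images) == 0) {
    abort_emofc("empty training set", class = "emofc_config_error")
  }
  x <- flatten_images(images)
  if (!all(is.finite(x))) {
    abort_emofc("non-finite feature values", class = "emofc_config_error")
  }
  y <- factor(as.character(y), levels = class_levels())
  fit <- with_seed(derive_seed(seed, 29L), {
    if (kind == "svm") {
      e1071::svm(x, y, kernel = "radial", scale = FALSE)
    } else {
      randomForest::randomForest(x, y, ntree = 200)
    }
  })
  structure(list(kind = kind, fit = fit), class = "emofc_baseline")
}

#' @export
predict.emofc_baseline <- function(object, images, ...) {
  x <- flatten_images(images)
  factor(as.character(predict(object$fit, x)), levels = class_levels())
}

# train + predict one model on one fold; returns predicted labels
fit_and_predict <- function(model, images, y, split, cfg, seed) {
  if (model %in% c("mini", "xception")) {
    scale <- if (model == "xception") "full" else "mini"
    cfg <- cfg %||% model_config(scale = scale)
    cfg$scale <- scale
    cfg$seed <- derive_seed(seed, 101L)
    fit <- train_cnn(images[split$train], y[split$train],
      images[split$val], y[split$val],
      cfg = cfg
    )
    predict(fit, images[split$test])
  } else {
    fit <- train_baseline(model, images[c(split$train, split$val)],
      y[c(split$train, split$val)],
      seed = seed
    )
    predict(fit, images[split$test])
  }
}

#' Cross-validated classification of encoded samples
#'
#' Runs k-fold cross-validation (default fivefold) of the chosen
#' classifier over a tibble of encoded samples, tallying per-fold
#' confusion counts and metrics. With `split_by = "sample"` (the
#' protocol's procedure) samples are partitioned irrespective of subject,
#' which leaks subject identity across folds; `split_by = "subject"`
#' keeps every subject's samples in a single part.
#'
#' @param samples Tibble with list-column `image` and column `label`
#'   (e.g. from [encode_samples()]), plus `subject` if splitting by
#'   subject.
#' @param model `"mini"`, `"xception"`, `"svm"` or `"rf"`.
#' @param k Number of folds.
#' @param seed Seed for fold assignment and training.
#' @param cfg Optional [model_config()] overriding CNN defaults.
#' @param channels Optional channel-label subset: image rows are
#'   restricted to these montage labels before training.
#' @param split_by `"sample"` (default; the protocol's procedure),
#'   `"subject"` (no subject leakage) or `"trial"` (samples of one trial
#'   stay in one part; removes trial-memorization leakage while keeping
#'   subjects shared).
#' @return Tibble of class `cv_result`: one row per fold with confusion
#'   counts and metrics.
#' @export
cross_validate <- function(samples, model = c("mini", "xception", "svm", "rf"),
                           k = 5, seed = 1L, cfg = NULL, channels = NULL,
                           split_by = c("sample", "subject", "trial")) {
  model <- match.arg(model)
  split_by <- match.arg(split_by)
  images <- samples$image
  y <- factor(as.character(samples$label), levels = class_levels())
  if (!is.null(channels)) {
    # restrict to the subset BEFORE pixel encoding: the min-max scale of
    # an image must be computed over the selected channels only,
    # otherwise out-of-subset channels leak through the normalization
    source_mats <- if ("x" %in% names(samples)) samples$x else images
    images <- lapply(source_mats, function(m) {
      missing <- setdiff(channels, rownames(m))
      if (length(missing) > 0) {
        abort_emofc(sprintf("channel(s) missing from samples: %s",
          paste(missing, collapse = ", ")), class = "emofc_config_error")
      }
      encode_image(m[channels, , drop = FALSE])
    })
  }
  if (split_by != "sample") {
    grp <- if (split_by == "subject") {
      as.character(samples$subject)
    } else {
      paste(samples$subject, samples$trial, sep = "_")
    }
    gu <- unique(grp)
    glab <- vapply(gu, function(g) {
      as.character(y[match(g, grp)])
    }, character(1))
    sf <- make_folds(glab, k = k, seed = seed)
    parts <- sf$part[match(grp, gu)]
    folds <- tibble::tibble(
      idx = seq_along(y), label = as.character(y),
      part = parts
    )
  } else {
    folds <- make_folds(y, k = k, seed = seed)
  }
  rows <- lapply(seq_len(k), function(f) {
    split <- fold_split(folds, f, k)
    pred <- fit_and_predict(model, images, y, split, cfg,
      seed = derive_seed(seed, f)
    )
    counts <- confusion_counts(y[split$test], pred)
    dplyr::bind_cols(
      tibble::tibble(fold = f, model = model),
      counts, compute_metrics(counts)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cv_result", class(out))
  out
}

#' Summarise a cross-validation run as mean and SD across folds
#'
#' @param x A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @return One-row tibble with per-metric mean and SD, mirroring the
#'   "71.16 +/- 3.67" reporting convention.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  metrics <- c("accuracy", "sensitivity", "specificity", "precision", "f1")
  out <- tibble::tibble(model = x$model[1], folds = nrow(x))
  for (m in metrics) {
    out[[paste0(m, "_mean")]] <- mean(x[[m]], na.rm = TRUE)
    out[[paste0(m, "_sd")]] <- sd(x[[m]], na.rm = TRUE)
  }
  out
}

#' @describeIn glance.cv_result Long per-fold metric table.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(x, "fold", "model", "accuracy", "sensitivity",
      "specificity", "precision", "f1"),
    cols = c("accuracy", "sensitivity", "specificity", "precision", "f1"),
    names_to = "metric", values_to = "value"
  )
}
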