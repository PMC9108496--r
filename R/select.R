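# Sequential backward selection over channel subsets with a pluggable
# evaluator (subset of labels -> accuracy).

#' Sequential backward channel selection
#'
#' Starting from `start` (typically the 8 frontal channels), every
#' leave-one-out subset of the current set is scored by `evaluator`; the
#' best-scoring subset becomes current, and the search shrinks one
#' channel per level down to `min_size` channels. The full accuracy grid
#' (every evaluated removal at every level) is recorded, and the best
#' subset is the argmax over all evaluated subsets at any level — the
#' optimum may be found mid-search. From 8 channels down to 2 the
#' evaluator runs 8+7+6+5+4+3 = 33 times.
#'
#' Ties between removals are broken deterministically in favour of
#' removing the channel with the larger montage index; ties are recorded
#' in the trace.
#'
#' @param start Character vector of starting channel labels.
#' @param evaluator Function taking a character vector of channel labels
#'   and returning a scalar accuracy. Must be deterministic for a given
#'   subset (e.g. reuse one fold seed across calls).
#' @param min_size Smallest subset size to evaluate (default 2).
#' @param montage Montage order used for tie-breaking.
#' @return Object of class `selection_trace`: `trace` (tibble with one
#'   row per evaluation: level, current subset, removed channel,
#'   resulting subset, accuracy, tie flag), `best_subset`,
#'   `best_accuracy`, `path` (the greedy sequence of current subsets).
#' @export
backward_select <- function(start, evaluator, min_size = 2,
                            montage = montage_32()) {
  start <- as.character(start)
  if (anyDuplicated(start) > 0 || length(start) == 0) {
    abort_emofc("`start` must be a non-empty set of unique labels",
      class = "emofc_config_error"
    )
  }
  if (length(start) <= min_size) {
    abort_emofc("`start` must be larger than `min_size`",
      class = "emofc_config_error"
    )
  }
  current <- start
  rows <- list()
  path <- list(start)
  level <- 0L
  while (length(current) > min_size) {
    level <- level + 1L
    cand <- lapply(seq_along(current), function(i) current[-i])
    acc <- vapply(seq_along(cand), function(i) {
      a <- tryCatch(evaluator(cand[[i]]), error = function(e) {
        abort_emofc(
          sprintf(
            "evaluator failed at level %d removing %s: %s",
            level, current[i], conditionMessage(e)
          ),
          class = "emofc_evaluator_error"
        )
      })
      as.numeric(a)
    }, numeric(1))
    best_acc <- max(acc)
    tied <- which(acc == best_acc)
    # tie-break: remove the channel with the larger montage index
    pick <- tied[which.max(match(current[tied], montage))]
    cur_str <- paste(current, collapse = "_")
    removed_vec <- current
    rows[[level]] <- tibble::tibble(
      level = level,
      n_channels = length(removed_vec) - 1L,
      current = cur_str,
      removed = removed_vec,
      subset = vapply(cand, paste, character(1), collapse = "_"),
      accuracy = acc,
      chosen = seq_along(cand) == pick,
      tie = length(tied) > 1
    )
    current <- cand[[pick]]
    path[[level + 1L]] <- current
  }
  trace <- dplyr::bind_rows(rows)
  best_row <- trace[which.max(trace$accuracy), ]
  structure(
    list(
      trace = trace,
      best_subset = strsplit(best_row$subset, "_", fixed = TRUE)[[1]],
      best_accuracy = best_row$accuracy,
      path = path
    ),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf(
    "<selection_trace> %d evaluations over %d levels\n",
    nrow(x$trace), max(x$trace$level)
  ))
  cat(sprintf(
    "  best subset (%d ch): %s  accuracy %.4f\n",
    length(x$best_subset), paste(x$best_subset, collapse = ", "),
    x$best_accuracy
  ))
  invisible(x)
}

#' Selection trace as a removal-accuracy grid
#'
#' Pivots the trace into the grid form used to report backward selection:
#' one row per level (current subset), one column per removed channel.
#'
#' @param x A `selection_trace`.
#' @param ... Unused.
#' @return Tibble: `current` plus one `remove_<label>` column per channel.
#' @method tidy selection_trace
#' @export
tidy.selection_trace <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::select(x$trace, "current", "removed", "accuracy"),
    names_from = "removed", values_from = "accuracy",
    names_prefix = "remove_"
  )
}

#' @describeIn tidy.selection_trace One-row summary of the search.
#' @method glance selection_trace
#' @export
glance.selection_trace <- function(x, ...) {
  tibble::tibble(
    evaluations = nrow(x$trace),
    levels = max(x$trace$level),
    best_size = length(x$best_subset),
    best_subset = paste(x$best_subset, collapse = "_"),
    best_accuracy = x$best_accuracy,
    ties = sum(x$trace$tie & x$trace$chosen)
  )
}

#' Build a cross-validation evaluator for the channel search
#'
#' Returns a closure mapping a channel subset to the mean k-fold CV test
#' accuracy (fraction in \[0, 1\]) of the chosen model on the given
#' samples, restricted to that subset's image rows. The fold seed is
#' fixed inside the closure so every subset is compared on identical
#' folds.
#'
#' @inheritParams cross_validate
#' @param samples Encoded samples tibble (list-column `image`, `label`).
#' @param split_by Fold grouping passed to [cross_validate()].
#' @return Function `(channels) -> accuracy`.
#' @export
make_cv_evaluator <- function(samples, model = "mini", k = 5, seed = 1L,
                              cfg = NULL, split_by = "sample") {
  force(samples)
  function(channels) {
    cv <- cross_validate(samples,
      model = model, k = k, seed = seed,
      cfg = cfg, channels = channels, split_by = split_by
    )
    mean(cv$accuracy) / 100
  }
}
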