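# ggplot2 displays for the main result types.

#' Plot a functional-connectivity matrix
#'
#' @param object A `coherence_matrix`.
#' @param ... Unused.
#' @return A ggplot heatmap of pairwise coherence.
#' @method autoplot coherence_matrix
#' @export
autoplot.coherence_matrix <- function(object, ...) {
  labs <- rownames(object)
  df <- expand.grid(ch_a = labs, ch_b = labs, stringsAsFactors = FALSE)
  df$coherence <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$ch_b, labs),
    y = factor(.data$ch_a, rev(labs)), fill = .data$coherence
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "coherence",
      title = "Functional connectivity (magnitude coherence)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a backward-selection accuracy grid
#'
#' @param object A `selection_trace`.
#' @param ... Unused.
#' @return A ggplot tile grid: levels (current subsets) by removed
#'   channel, filled by accuracy; the chosen removal per level is
#'   outlined.
#' @method autoplot selection_trace
#' @export
autoplot.selection_trace <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(
    x = .data$removed,
    y = factor(.data$current, rev(unique(.data$current))),
    fill = .data$accuracy
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = tr[tr$chosen, ], fill = NA,
      colour = "red", linewidth = 0.8
    ) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", 100 * .data$accuracy)
    ), size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "removed channel", y = "current subset",
      fill = "accuracy",
      title = "Sequential backward channel selection"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the dynamic-connectivity classification curve
#'
#' @param object An `fc_curve` from [dynamic_classification_curve()].
#' @param ... Unused.
#' @return A ggplot line chart of accuracy and F1 against the number of
#'   concatenated trials.
#' @method autoplot fc_curve
#' @export
autoplot.fc_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "trials", "accuracy_mean", "f1_mean"),
    cols = -"trials", names_to = "metric", values_to = "value"
  )
  df$metric <- sub("_mean$", "", df$metric)
  ggplot2::ggplot(df, ggplot2::aes(.data$trials, .data$value,
    colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "concatenated trials (k)", y = "mean CV metric (%)",
      title = "Dynamic functional-connectivity classification"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-state mean connectivity comparison
#'
#' @param object An `fc_comparison`.
#' @param ... Unused.
#' @return A ggplot of per-subject mean Fisher-z coherence by state with
#'   paired lines.
#' @method autoplot fc_comparison
#' @export
autoplot.fc_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(object$subject_means,
    cols = c("HVA", "LVA"),
    names_to = "state", values_to = "z"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$state, .data$z)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject),
      colour = "grey70"
    ) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
      colour = "red") +
    ggplot2::labs(
      y = "subject mean Fisher-z coherence",
      title = sprintf(
        "Mean frontal FC by state (paired t = %.2f, p = %.3g)",
        object$t, object$p
      )
    ) +
    ggplot2::theme_minimal()
}
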