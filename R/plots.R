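# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_abline labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a layer trend with its fitted line
#'
#' @param object A `layer_trend`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.layer_trend <- function(object, ...) {
  prof <- object$profile |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(index = layer_index(.data$layer)) |>
    dplyr::arrange(.data$index)
  ab <- coef(object$fit)
  ggplot(prof, aes(x = .data$index, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
                alpha = 0.2) +
    geom_line() +
    geom_point() +
    geom_abline(intercept = ab[1], slope = ab[2], linetype = 2) +
    ggplot2::scale_x_continuous(breaks = 0:5, labels = ANALYZED_LAYERS) +
    labs(x = "network layer", y = "metric",
         title = sprintf("slope %.3g per layer step (t(%d) = %.2f)",
                         object$slope, object$df, object$statistic)) +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_result` from [lda_classify()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = 3) +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' Plot cumulative variance explained across layers
#'
#' @param cumvar Tibble from [cumulative_variance()].
#' @param baseline Optional tibble from [random_baseline()], drawn in grey.
#' @return A ggplot object.
#' @export
plot_cumulative_variance <- function(cumvar, baseline = NULL) {
  cumvar$index <- seq_len(nrow(cumvar)) - 1L
  p <- ggplot(cumvar, aes(x = .data$index, y = .data$cumulative)) +
    geom_line() + geom_point() +
    ggplot2::scale_x_continuous(breaks = cumvar$index, labels = cumvar$layer) +
    labs(x = "network layer", y = "cumulative variance explained") +
    theme_minimal()
  if (!is.null(baseline)) {
    baseline$index <- seq_len(nrow(baseline)) - 1L
    p <- p + geom_line(data = baseline, colour = "grey55", linetype = 2) +
      geom_point(data = baseline, colour = "grey55")
  }
  p
}

#' Plot a salience curve with detected events
#'
#' @param curve Salience tibble (`time`, `percent`).
#' @param events Optional event tibble (`time_s`).
#' @return A ggplot object.
#' @export
plot_salience <- function(curve, events = NULL) {
  p <- ggplot(curve, aes(x = .data$time, y = .data$percent)) +
    geom_line() +
    labs(x = "time (s)", y = "% subjects attending") +
    theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = events$time_s,
                                 colour = "firebrick", linetype = 3)
  }
  p
}
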