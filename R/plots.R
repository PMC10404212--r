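#' ROC curve of a streamed run
#'
#' Plots the ROC sweep underlying the trapezoidal AUC of a `stream_report`.
#'
#' @param object A `stream_report` from [stream_run()].
#' @param positive Positive-class label (default `"client"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stream_report <- function(object, positive = "client", ...) {
  rec <- object$records
  truth <- rec$truth == positive
  ord <- order(rec$score, decreasing = TRUE)
  y <- truth[ord]; s <- rec$score[ord]
  last <- c(s[-1L] != s[-length(s)], TRUE)
  df <- tibble::tibble(fpr = c(0, cumsum(!y)[last] / sum(!truth)),
                       tpr = c(0, cumsum(y)[last] / sum(truth)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (%s/%s), AUC = %.3f", object$classifier,
                      object$strategy, object$metrics$auc)) +
    ggplot2::theme_minimal()
}

#' Metric comparison across update strategies
#'
#' Per-run metric values (points) and configuration means (bars) per metric
#' facet, mirroring the usual strategy-comparison figures.
#'
#' @param object A `strategy_comparison` from [compare_strategies()].
#' @param metrics Which metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strategy_comparison <- function(object,
                                         metrics = c("auc", "recall",
                                                     "precision", "f_measure"),
                                         ...) {
  long <- tidyr::pivot_longer(object$runs, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$config, y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "col", alpha = 0.4) +
    ggplot2::geom_jitter(width = 0.1, size = 0.8, alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Incremental update strategies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
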