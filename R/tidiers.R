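#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-object records of a streamed run
#'
#' @param x A `stream_report` from [stream_run()].
#' @param ... Unused.
#' @return A tibble with one row per streamed object (`truth`, `predicted`,
#'   `score`).
#' @export
tidy.stream_report <- function(x, ...) x$records

#' One-row summary of a streamed run
#'
#' @param x A `stream_report`.
#' @param ... Unused.
#' @return A one-row tibble: metrics plus pool bookkeeping.
#' @export
glance.stream_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(classifier = x$classifier, strategy = x$strategy),
    x$metrics,
    tibble::tibble(initial_size = x$initial_size, final_size = x$final_size,
                   insertions = x$insertions, deletions = x$deletions))
}

#' Tidy per-run metrics of a strategy comparison
#'
#' @param x A `strategy_comparison` from [compare_strategies()].
#' @param ... Unused.
#' @return The per seed x fold x configuration metric tibble.
#' @export
tidy.strategy_comparison <- function(x, ...) x$runs

#' Mean metrics per configuration
#'
#' @param x A `strategy_comparison`.
#' @param ... Unused.
#' @return One row per configuration.
#' @export
glance.strategy_comparison <- function(x, ...) x$summary

#' Tidy a paired t-test
#'
#' @param x A `paired_test` from [paired_t()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.paired_test <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff, n = x$n,
                 statistic = x$t, p_value = x$p_value,
                 significant = x$significant)
}
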