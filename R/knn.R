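#' Configuration for the FIFO-windowed KNN baseline
#'
#' Emulates an incremental instance-based (IBk-style) classifier: plain
#' Euclidean KNN with majority vote, always inserting the streamed object and
#' evicting the oldest objects when a window cap is set.
#'
#' @param k Number of neighbours (default 5).
#' @param window_size Pool cap; 0 = unlimited.
#' @param insert_label_mode `"predicted"` (no ground truth available at
#'   authentication time, the default) or `"actual"`.
#' @return A list of class `knn_config`.
#' @export
knn_config <- function(k = 5, window_size = 0,
                       insert_label_mode = c("predicted", "actual")) {
  insert_label_mode <- match.arg(insert_label_mode)
  stopifnot(k >= 1, window_size >= 0)
  structure(list(k = as.integer(k), window_size = as.integer(window_size),
                 insert_label_mode = insert_label_mode),
            class = "knn_config")
}

#' K-nearest-neighbour prediction with majority vote
#'
#' Euclidean distance on raw feature values; the k nearest objects vote with
#' equal weight (no distance weighting). A tied vote falls back to the class
#' of the single nearest neighbour. The score is the fraction of votes for
#' the positive class, for ROC ranking.
#'
#' @param pool An [frnn_pool()].
#' @param y Numeric test vector.
#' @param k Number of neighbours (default 5).
#' @param positive Label treated as the positive class for the score
#'   (default `"client"`).
#' @return A list with `predicted`, `score`, and `neighbours` (pool rows).
#' @export
knn_predict <- function(pool, y, k = 5, positive = "client") {
  n <- pool_size(pool)
  if (n == 0L) stop("empty pool", call. = FALSE)
  d <- .euclidean_scan(pool$X, as.numeric(y))
  ord <- order(d, pool$insertion_index)
  take <- ord[seq_len(min(k, n))]
  labs <- pool$labels[take]
  votes <- table(labs)
  top <- names(votes)[votes == max(votes)]
  predicted <- if (length(top) == 1L) top else labs[1L]
  list(predicted = predicted,
       score = mean(labs == positive),
       neighbours = take)
}

#' First-in-first-out pool update
#'
#' Always inserts the streamed object, then removes the oldest objects
#' (smallest insertion index, blind to labels and usage) while the pool
#' exceeds the window cap. On an imbalanced stream this can evict every
#' positive-class object — the failure mode that motivates counter-based
#' deletion.
#'
#' @param pool An [frnn_pool()].
#' @param y Numeric feature vector.
#' @param label Label to store (chosen per the config's `insert_label_mode`
#'   by the caller).
#' @param config A [knn_config()].
#' @return The updated pool.
#' @export
apply_fifo_update <- function(pool, y, label, config = knn_config()) {
  pool <- pool_insert(pool, y, label)
  if (config$window_size > 0L) {
    while (pool_size(pool) > config$window_size) {
      oldest <- which.min(pool$insertion_index)
      pool$X <- pool$X[-oldest, , drop = FALSE]
      pool$labels <- pool$labels[-oldest]
      pool$counter <- pool$counter[-oldest]
      pool$insertion_index <- pool$insertion_index[-oldest]
    }
  }
  pool
}
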