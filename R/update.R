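#' Configuration for incremental update strategies
#'
#' @param k Number of nearest neighbours used for classification and counter
#'   updates (default 5).
#' @param window_size Cap on the training-pool size; 0 means unlimited. When
#'   the pool exceeds the cap after an insertion, least-used objects are
#'   evicted until the cap holds.
#' @param strategy One of `"probability"` (insertion decided from the
#'   neighbour-similarity threshold and class probabilities, no ground truth
#'   used), `"actual_class"` (insert on misclassification, requires the true
#'   label), or `"none"` (static pool).
#' @return A list of class `update_config`.
#' @export
update_config <- function(k = 5, window_size = 0,
                          strategy = c("probability", "actual_class", "none")) {
  strategy <- match.arg(strategy)
  stopifnot(k >= 1, window_size >= 0)
  structure(list(k = as.integer(k), window_size = as.integer(window_size),
                 strategy = strategy),
            class = "update_config")
}

#' Relative difference of two similarities
#'
#' The percentage difference `(sim_a - sim_b) / ((sim_a + sim_b) / 2)` between
#' two consecutive entries of a descending similarity list; 0 when both are 0.
#'
#' @param sim_a,sim_b Similarities with `sim_a >= sim_b >= 0`.
#' @return Non-negative relative difference (at most 2).
#' @export
relative_difference <- function(sim_a, sim_b) {
  if (any(sim_a < sim_b)) stop("similarities not in descending order", call. = FALSE)
  denom <- (sim_a + sim_b) / 2
  ifelse(denom == 0, 0, (sim_a - sim_b) / denom)
}

#' Insertion threshold from a neighbour similarity list
#'
#' Half the sum of the relative differences over all consecutive pairs of the
#' descending similarity list. The list should contain k + 1 similarities when
#' the pool allows, so that the sum runs over k pairs; on smaller pools the
#' sum simply has fewer terms.
#'
#' @param sims Numeric vector of similarities, sorted descending, length >= 2.
#' @return The threshold (non-negative).
#' @export
insertion_threshold <- function(sims) {
  if (length(sims) < 2L) stop("need at least two similarities", call. = FALSE)
  pairs <- relative_difference(sims[-length(sims)], sims[-1L])
  0.5 * sum(pairs)
}

#' Class probabilities from neighbour usage counters
#'
#' For each class C present in the pool:
#' `P(C) = [(sum of counters of neighbours in C) / (sum of counters of all
#' neighbours)] / (sum of counters of all pool objects in C)`. The values are
#' not a normalised distribution; only their argmax is used by the insertion
#' decision.
#'
#' @param pool An [frnn_pool()].
#' @param neighbour_ids Pool row positions of the nearest neighbours.
#' @return Named numeric vector over the pool's class set.
#' @export
class_probabilities <- function(pool, neighbour_ids) {
  if (length(neighbour_ids) == 0L) stop("no neighbours", call. = FALSE)
  cls <- pool$class_set
  nn_labs <- pool$labels[neighbour_ids]
  nn_cnt <- pool$counter[neighbour_ids]
  tot_nn <- sum(nn_cnt)
  p <- vapply(cls, function(ci) {
    num <- sum(nn_cnt[nn_labs == ci]) / tot_nn
    mass <- sum(pool$counter[pool$labels == ci])
    if (mass == 0) 0 else num / mass
  }, numeric(1))
  stats::setNames(p, cls)
}

#' Object-insertion decision
#'
#' An object is inserted when either (1) the top-two neighbour difference D
#' exceeds the threshold and the predicted class differs from the
#' highest-probability class, or (2) D is below the threshold and the
#' predicted class agrees with the highest-probability class. `D == threshold`
#' exactly inserts nothing (both conditions are strict).
#'
#' @param D Relative difference between the top two neighbour similarities.
#' @param threshold Value from [insertion_threshold()].
#' @param predicted Predicted class label.
#' @param best_prob_class Class with the highest probability.
#' @return Logical.
#' @export
decide_insertion <- function(D, threshold, predicted, best_prob_class) {
  stopifnot(D >= 0, threshold >= 0)
  (D > threshold && predicted != best_prob_class) ||
    (D < threshold && predicted == best_prob_class)
}

# Shared window-capped deletion loop. Returns list(pool, deleted_indices).
.apply_window <- function(pool, window_size) {
  deleted <- integer(0)
  if (window_size > 0L) {
    while (pool_size(pool) > window_size) {
      ord <- order(pool$counter, pool$insertion_index)
      deleted <- c(deleted, pool$insertion_index[ord[1L]])
      pool <- pool_delete_least_used(pool)
    }
  }
  list(pool = pool, deleted = deleted)
}

# Pick the highest-probability class; ties keep the predicted class when it
# is among the maxima, else the lexicographically first.
.best_prob_class <- function(probs, predicted) {
  mx <- max(probs)
  tied <- sort(names(probs)[probs == mx])
  if (predicted %in% tied) predicted else tied[1L]
}

#' Probability-based incremental update
#'
#' The label-free update applied after classifying one streamed object:
#' retrieves `min(k + 1, pool size)` neighbours, computes the top-two relative
#' difference D and the insertion threshold from the full retrieved list,
#' computes class probabilities from the usage counters as they stand before
#' this object's update, then increments the counters of the top k
#' neighbours, inserts the object under its *predicted* label when
#' [decide_insertion()] fires, and finally enforces the window cap by
#' least-used deletion. With fewer than two pooled objects the similarity
#' structure needed by the threshold does not exist, so the object is
#' inserted unconditionally (cold start).
#'
#' @param pool An [frnn_pool()].
#' @param y Numeric feature vector of the streamed object.
#' @param scores Result of [frnn_predict()] on `pool` and `y` (or `NULL` to
#'   compute internally).
#' @param config An [update_config()].
#' @return A list with elements `pool` (updated) and `context`, a one-row
#'   tibble audit record (D, threshold, probabilities, decision, evictions).
#' @export
apply_probability_update <- function(pool, y, scores = NULL, config = update_config()) {
  y <- as.numeric(y)
  k <- config$k
  if (pool_size(pool) < 2L) {
    lab <- if (is.null(scores)) pool$labels[1L] else attr(scores, "predicted")
    if (pool_size(pool) == 0L) stop("empty pool", call. = FALSE)
    pool <- pool_insert(pool, y, lab)
    ctx <- tibble::tibble(D = NA_real_, threshold = NA_real_,
                          predicted = lab, best_prob_class = NA_character_,
                          inserted = TRUE, n_deleted = 0L)
    return(list(pool = pool, context = ctx))
  }
  if (is.null(scores)) scores <- frnn_predict(pool, y, k)
  predicted <- attr(scores, "predicted")
  nn <- .neighbour_scan(pool, y, k + 1L)
  sims <- nn$sims
  D <- relative_difference(sims[1L], sims[2L])
  thr <- insertion_threshold(sims)
  top_k <- nn$ids[seq_len(min(k, length(nn$ids)))]
  probs <- class_probabilities(pool, top_k)
  best <- .best_prob_class(probs, predicted)
  pool <- increment_usage(pool, top_k)
  ins <- decide_insertion(D, thr, predicted, best)
  if (ins) pool <- pool_insert(pool, y, predicted)
  win <- .apply_window(pool, config$window_size)
  ctx <- tibble::tibble(D = D, threshold = thr, predicted = predicted,
                        best_prob_class = best, inserted = ins,
                        n_deleted = length(win$deleted))
  list(pool = win$pool, context = ctx)
}

#' Actual-class (ground-truth) incremental update
#'
#' The reference update strategy: the streamed object is inserted under its
#' true label when it was misclassified; the usage counters of the k nearest
#' neighbours are incremented; the window cap is then enforced by least-used
#' deletion. Requires ground truth, so it represents an upper bound rather
#' than a deployable authentication strategy.
#'
#' @inheritParams apply_probability_update
#' @param predicted Predicted class label for `y`.
#' @param actual True class label for `y`.
#' @return The updated pool.
#' @export
apply_actual_class_update <- function(pool, y, predicted, actual,
                                      config = update_config(strategy = "actual_class")) {
  y <- as.numeric(y)
  nn <- .neighbour_scan(pool, y, min(config$k, pool_size(pool)))
  pool <- increment_usage(pool, nn$ids)
  if (!identical(predicted, actual)) pool <- pool_insert(pool, y, actual)
  .apply_window(pool, config$window_size)$pool
}
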