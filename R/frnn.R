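#' Per-attribute fuzzy similarity
#'
#' Normalised similarity between two attribute values,
#' `1 - |a_x - a_y| / (a_max - a_min)`, the building block of the fuzzy
#' tolerance relation. Inputs are clamped into the recorded attribute range
#' before use; a zero-range (constant) attribute has similarity 1, since an
#' attribute that never varies carries no discriminating information.
#'
#' @param a_x,a_y Attribute values (numeric).
#' @param a_min,a_max Recorded minimum and maximum of the attribute.
#' @return Similarity in \[0, 1\] (vectorised over the value arguments).
#' @export
attr_similarity <- function(a_x, a_y, a_min, a_max) {
  if (any(!is.finite(c(a_x, a_y, a_min, a_max)))) {
    stop("non-finite input", call. = FALSE)
  }
  if (any(a_min > a_max)) stop("a_min > a_max", call. = FALSE)
  rng <- a_max - a_min
  a_x <- pmin(pmax(a_x, a_min), a_max)
  a_y <- pmin(pmax(a_y, a_min), a_max)
  ifelse(rng <= 0, 1, 1 - abs(a_x - a_y) / rng)
}

#' Fuzzy tolerance relation between two objects
#'
#' The graded indiscernibility R(x, y): the minimum over attributes of the
#' per-attribute similarity, each normalised by the pool's recorded attribute
#' range.
#'
#' @param x,y Numeric feature vectors of equal length.
#' @param a_min,a_max Per-attribute range vectors (recycled if scalar).
#' @return A single similarity in \[0, 1\].
#' @export
tolerance <- function(x, y, a_min, a_max) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  a_min <- rep_len(a_min, length(x))
  a_max <- rep_len(a_max, length(x))
  min(attr_similarity(x, y, a_min, a_max))
}

#' Nearest neighbours under the fuzzy tolerance relation
#'
#' Ranks pool objects by tolerance similarity to a test vector, descending;
#' equal similarities are broken in favour of the older object (smaller
#' insertion index) so rankings are deterministic.
#'
#' @param pool An [frnn_pool()].
#' @param y Numeric test vector.
#' @param k Number of neighbours requested (truncated to the pool size).
#' @return A tibble with columns `id` (pool row), `insertion_index`,
#'   `class`, `similarity`, sorted by decreasing similarity.
#' @export
nearest_neighbours <- function(pool, y, k) {
  nn <- .neighbour_scan(pool, y, k)
  tibble::tibble(
    id = nn$ids,
    insertion_index = pool$insertion_index[nn$ids],
    class = pool$labels[nn$ids],
    similarity = nn$sims
  )
}

# Fast internal neighbour retrieval: list(ids, sims), descending similarity,
# ties by insertion order.
.neighbour_scan <- function(pool, y, k) {
  n <- pool_size(pool)
  if (n == 0L) stop("empty pool", call. = FALSE)
  stopifnot(k >= 1L)
  sims <- .tolerance_scan(pool$X, as.numeric(y), pool$a_min, pool$a_max)
  ord <- order(-sims, pool$insertion_index)
  take <- ord[seq_len(min(k, n))]
  list(ids = take, sims = sims[take])
}

#' Fuzzy-rough nearest neighbour prediction
#'
#' Classifies a test vector from its k nearest neighbours under the fuzzy
#' tolerance relation. For each class C the lower approximation membership is
#' `min over neighbours x of I(R(x,y), C(x))` with the Kleene–Dienes
#' implicator `I(a, b) = max(1 - a, b)`, and the upper approximation is
#' `max over neighbours of T(R(x,y), C(x))` with the minimum t-norm
#' `T(a, b) = min(a, b)`; class membership C(x) is crisp 0/1. A high lower
#' membership means all neighbours belong to the class; a high upper
#' membership means at least one does. The predicted class maximises
#' `(lower + upper) / 2`; score ties prefer the larger upper membership, then
#' lexicographic label order.
#'
#' @param pool An [frnn_pool()] with at least one object.
#' @param y Numeric test vector.
#' @param k Number of neighbours (default 5).
#' @return An object of class `frnn_scores`: a tibble with columns `class`,
#'   `lower`, `upper`, `score`, plus attributes `predicted` and `neighbours`.
#' @examples
#' tbl <- tibble::tibble(f1 = c(0, 0.1, 1), f2 = c(0, 0.1, 1),
#'                       class = c("a", "a", "b"))
#' p <- frnn_pool(tbl)
#' frnn_predict(p, c(0.05, 0.05), k = 2)
#' @export
frnn_predict <- function(pool, y, k = 5) {
  res <- .frnn_scores(pool, as.numeric(y), as.integer(k))
  out <- tibble::tibble(class = res$classes, lower = res$lower,
                        upper = res$upper, score = res$score)
  attr(out, "predicted") <- res$predicted
  attr(out, "neighbours") <- res$nn_ids
  class(out) <- c("frnn_scores", class(out))
  out
}

#' @export
print.frnn_scores <- function(x, ...) {
  cat("FRNN class scores (predicted: ", attr(x, "predicted"), ")\n", sep = "")
  NextMethod()
}

# Internal scoring path shared with the stream runner. Returns plain vectors.
.frnn_scores <- function(pool, y, k) {
  nn <- .neighbour_scan(pool, y, k)
  cls <- pool$class_set
  labs <- pool$labels[nn$ids]
  sims <- nn$sims
  nl <- length(cls)
  lower <- numeric(nl)
  upper <- numeric(nl)
  for (i in seq_len(nl)) {
    memb <- as.numeric(labs == cls[i])
    lower[i] <- min(pmax(1 - sims, memb))
    upper[i] <- max(pmin(sims, memb))
  }
  score <- (lower + upper) / 2
  # argmax of score; ties -> larger upper, then lexicographic class order
  ord <- order(-score, -upper, cls)
  list(classes = cls, lower = lower, upper = upper, score = score,
       predicted = cls[ord[1L]], nn_ids = nn$ids, nn_sims = sims)
}
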