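#' Training pools of labelled objects
#'
#' The training pool is the mutable knowledge granule of the incremental
#' classifiers: an ordered set of labelled feature vectors, each carrying a
#' usage `counter` (incremented whenever the object serves as a nearest
#' neighbour) and an `insertion_index` recording arrival order. The pool also
#' tracks the per-attribute minimum and maximum observed values, which
#' normalise the fuzzy tolerance relation.
#'
#' `frnn_pool()` builds a pool from a data frame with feature columns and a
#' class column. Counters start at 1 so that the per-class counter mass in the
#' class-probability formula can never be zero for a class that is present.
#'
#' @param data A data frame or tibble of numeric feature columns plus one
#'   class column.
#' @param class_col Name of the class column (default `"class"`).
#' @return An object of class `frnn_pool`.
#' @examples
#' tbl <- tibble::tibble(f1 = c(0, 1), f2 = c(1, 0), class = c("a", "b"))
#' p <- frnn_pool(tbl)
#' pool_size(p)
#' @export
frnn_pool <- function(data, class_col = "class") {
  stopifnot(is.data.frame(data))
  if (!class_col %in% names(data)) {
    stop("class column '", class_col, "' not found", call. = FALSE)
  }
  labels <- as.character(data[[class_col]])
  feats <- data[setdiff(names(data), class_col)]
  keep <- vapply(feats, is.numeric, logical(1))
  feats <- feats[keep]
  if (ncol(feats) < 1L) stop("no numeric feature columns", call. = FALSE)
  X <- as.matrix(feats)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  n <- nrow(X)
  pool <- structure(list(
    X = X,
    labels = labels,
    counter = rep(1L, n),
    insertion_index = if (n > 0L) 0:(n - 1L) else integer(0),
    next_index = n,
    a_min = if (n > 0L) apply(X, 2L, min) else rep(Inf, ncol(X)),
    a_max = if (n > 0L) apply(X, 2L, max) else rep(-Inf, ncol(X)),
    feature_names = colnames(X),
    class_set = sort(unique(labels))
  ), class = "frnn_pool")
  pool
}

#' @rdname frnn_pool
#' @param pool An `frnn_pool`.
#' @export
pool_size <- function(pool) nrow(pool$X)

#' @export
print.frnn_pool <- function(x, ...) {
  cat("<frnn_pool> ", pool_size(x), " objects, ", ncol(x$X), " attributes, classes: ",
      paste(x$class_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn frnn_pool One row per stored object: features, label, usage
#'   counter and insertion index.
#' @param x An `frnn_pool`.
#' @param ... Unused.
#' @export
as_tibble.frnn_pool <- function(x, ...) {
  tb <- tibble::as_tibble(as.data.frame(x$X))
  tb$class <- x$labels
  tb$counter <- x$counter
  tb$insertion_index <- x$insertion_index
  tb
}

#' Insert an object into a training pool
#'
#' Appends a feature vector with usage counter 1 and the next insertion
#' index; per-attribute min/max statistics are widened to cover the new
#' values so tolerance similarities stay in \[0, 1\].
#'
#' @param pool An `frnn_pool`.
#' @param features Numeric vector, one value per pool attribute.
#' @param label Class label (length-1 character).
#' @return The updated pool.
#' @export
pool_insert <- function(pool, features, label) {
  features <- as.numeric(features)
  if (length(features) != ncol(pool$X)) {
    stop("dimension mismatch: pool has ", ncol(pool$X), " attributes, got ",
         length(features), call. = FALSE)
  }
  if (any(!is.finite(features))) stop("non-finite feature value", call. = FALSE)
  label <- as.character(label)[1]
  pool$X <- rbind(pool$X, features, deparse.level = 0)
  pool$labels <- c(pool$labels, label)
  pool$counter <- c(pool$counter, 1L)
  pool$insertion_index <- c(pool$insertion_index, pool$next_index)
  pool$next_index <- pool$next_index + 1L
  pool$a_min <- pmin(pool$a_min, features)
  pool$a_max <- pmax(pool$a_max, features)
  if (!label %in% pool$class_set) pool$class_set <- sort(c(pool$class_set, label))
  pool
}

#' Delete the least-used object from a pool
#'
#' Removes the object with the lowest usage counter; ties are broken
#' first-in-first-out (smallest insertion index). Attribute range statistics
#' are kept widened by default: recomputing the exact min/max after every
#' deletion costs O(n d) per step, and widened ranges only rescale
#' similarities monotonically while keeping them in \[0, 1\].
#'
#' @param pool An `frnn_pool`, non-empty.
#' @param recompute_stats If `TRUE`, recompute exact per-attribute min/max
#'   after the deletion.
#' @return The updated pool.
#' @export
pool_delete_least_used <- function(pool, recompute_stats = FALSE) {
  n <- pool_size(pool)
  if (n == 0L) stop("cannot delete from an empty pool", call. = FALSE)
  ord <- order(pool$counter, pool$insertion_index)
  drop <- ord[1L]
  pool$X <- pool$X[-drop, , drop = FALSE]
  pool$labels <- pool$labels[-drop]
  pool$counter <- pool$counter[-drop]
  pool$insertion_index <- pool$insertion_index[-drop]
  if (recompute_stats && nrow(pool$X) > 0L) {
    pool$a_min <- apply(pool$X, 2L, min)
    pool$a_max <- apply(pool$X, 2L, max)
  }
  pool
}

#' Increment usage counters of pool objects
#'
#' @param pool An `frnn_pool`.
#' @param ids Integer row positions (1-based) of the objects that served as
#'   nearest neighbours.
#' @return The updated pool.
#' @export
increment_usage <- function(pool, ids) {
  if (length(ids) == 0L) return(pool)
  ids <- as.integer(ids)
  if (any(is.na(ids)) || any(ids < 1L) || any(ids > pool_size(pool))) {
    stop("unknown object id", call. = FALSE)
  }
  tab <- tabulate(ids, nbins = pool_size(pool))
  pool$counter <- pool$counter + tab
  pool
}

#' Read or write a pool snapshot as CSV
#'
#' One row per object: feature columns, `class`, `counter`,
#' `insertion_index`. Round-trips through [frnn_pool()] plus counter/index
#' restoration, for audit and resume.
#'
#' @param pool An `frnn_pool`.
#' @param path File path.
#' @return `write_pool_csv()` returns `path` invisibly; `read_pool_csv()`
#'   returns an `frnn_pool`.
#' @export
write_pool_csv <- function(pool, path) {
  utils::write.csv(as_tibble.frnn_pool(pool), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_csv
#' @export
read_pool_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  counters <- as.integer(df$counter)
  idx <- as.integer(df$insertion_index)
  df$counter <- NULL
  df$insertion_index <- NULL
  pool <- frnn_pool(df)
  pool$counter <- counters
  pool$insertion_index <- idx
  pool$next_index <- max(idx) + 1L
  pool
}
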