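#' Feature-class correlation
#'
#' Absolute Pearson (point-biserial) correlation between a continuous feature
#' and a binary class, the relevance term of the CFS merit. A constant
#' feature scores 0.
#'
#' @param values Numeric feature vector.
#' @param labels Class labels with exactly two distinct values.
#' @return Correlation magnitude in \[0, 1\].
#' @export
feature_class_correlation <- function(values, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need two classes", call. = FALSE)
  if (stats::sd(values) == 0) return(0)
  y <- as.numeric(labels == sort(unique(labels))[1L])
  abs(stats::cor(values, y))
}

#' CFS subset merit
#'
#' The correlation-based feature-selection heuristic
#' `Merit_S = k * r_cf / sqrt(k + k (k - 1) * r_ff)` for a subset of `k`
#' features with mean feature-class correlation `r_cf` and mean inter-feature
#' correlation `r_ff`: relevance in the numerator, redundancy in the
#' denominator.
#'
#' @param k Subset size (>= 1).
#' @param r_cf Mean absolute feature-class correlation.
#' @param r_ff Mean absolute feature-feature correlation (>= 0).
#' @return The merit value.
#' @export
cfs_merit <- function(k, r_cf, r_ff) {
  stopifnot(k >= 1, r_ff >= 0)
  denom <- sqrt(k + k * (k - 1) * r_ff)
  if (denom == 0) stop("zero denominator", call. = FALSE)
  k * r_cf / denom
}

#' Greedy forward CFS feature selection
#'
#' Best-first forward search over the CFS merit: starting from the empty
#' set, repeatedly add the feature that maximises the subset merit (ties
#' broken by lexicographic feature name), and stop after `patience`
#' consecutive additions fail to improve on the best merit seen. Returns the
#' best subset found (at least one feature, even on an all-noise table).
#'
#' @param table A data frame with numeric feature columns and a binary class
#'   column.
#' @param class_col Name of the class column (default `"class"`).
#' @param patience Consecutive non-improving expansions tolerated (default
#'   5).
#' @return Character vector of selected feature names, with the achieved
#'   merit as attribute `"merit"`.
#' @export
cfs_select <- function(table, class_col = "class", patience = 5) {
  stopifnot(is.data.frame(table), class_col %in% names(table))
  labels <- as.character(table[[class_col]])
  feats <- table[setdiff(names(table), class_col)]
  feats <- feats[vapply(feats, is.numeric, logical(1))]
  if (ncol(feats) < 2L) stop("need at least two features", call. = FALSE)
  if (length(unique(labels)) != 2L) stop("need a binary class", call. = FALSE)
  X <- as.matrix(feats)
  nm <- colnames(X)
  r_cf <- vapply(nm, function(f) feature_class_correlation(X[, f], labels),
                 numeric(1))
  cmat <- suppressWarnings(abs(stats::cor(X)))
  cmat[!is.finite(cmat)] <- 0  # constant features carry no correlation

  subset_merit <- function(sub) {
    k <- length(sub)
    rff <- if (k > 1L) mean(cmat[sub, sub][upper.tri(diag(k))]) else 0
    cfs_merit(k, mean(r_cf[sub]), rff)
  }

  subset <- character(0)
  best_subset <- character(0)
  best_merit <- -Inf
  stalls <- 0L
  candidates <- sort(nm)
  while (stalls < patience && length(subset) < length(nm)) {
    remaining <- setdiff(candidates, subset)
    merits <- vapply(remaining, function(f) subset_merit(c(subset, f)),
                     numeric(1))
    pick <- remaining[which.max(merits)]  # which.max takes the first tie ->
    subset <- c(subset, pick)             # lexicographic by sorted candidates
    m <- merits[pick]
    if (m > best_merit + 1e-12) {
      best_merit <- m
      best_subset <- subset
      stalls <- 0L
    } else {
      stalls <- stalls + 1L
    }
  }
  if (length(best_subset) == 0L) {  # all-noise: keep the single best feature
    best_subset <- subset[1L]
    best_merit <- subset_merit(best_subset)
  }
  structure(best_subset, merit = best_merit)
}
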