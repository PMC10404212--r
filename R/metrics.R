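#' Classification metrics for one streamed run
#'
#' Confusion counts and threshold metrics with the client (enrolled user)
#' as the positive class, plus the area under the ROC curve computed by
#' trapezoidal integration of the (FPR, TPR) sweep over score thresholds;
#' tied scores receive half credit, so the value equals the Mann-Whitney
#' pair-counting estimator. Under heavy class imbalance accuracy is dominated
#' by the impostor class, which is why recall, precision and F-measure are
#' reported alongside.
#'
#' @param records A data frame with columns `truth`, `predicted` (labels)
#'   and `score` (positive-class score for ranking).
#' @param positive Positive-class label (default `"client"`).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`, `recall`,
#'   `precision`, `f_measure`, `auc`.
#' @export
compute_metrics <- function(records, positive = "client") {
  truth <- as.character(records$truth) == positive
  pred <- as.character(records$predicted) == positive
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  tn <- sum(!truth & !pred); fn <- sum(truth & !pred)
  n <- length(truth)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / n,
    recall = recall, precision = precision, f_measure = f,
    auc = roc_auc(records$score, truth)
  )
}

#' Trapezoidal ROC area
#'
#' @param score Numeric positive-class scores.
#' @param truth Logical (or coercible) positive-class indicator.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(score, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) {
    stop("AUC undefined: need both classes", call. = FALSE)
  }
  np <- sum(truth); nn <- sum(!truth)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- truth[ord]
  # cumulative counts at each distinct threshold
  last <- c(s[-1L] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(y)[last] / np)
  fpr <- c(0, cumsum(!y)[last] / nn)
  sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

#' Anderson-Darling normality test
#'
#' Normality check applied to per-fold metric values before the paired
#' t-test, using the case-3 statistic (mean and variance estimated from the
#' sample) with its small-sample correction.
#'
#' @param values Numeric vector, n >= 8, non-constant.
#' @return A list with `A2` (the corrected statistic) and `p`.
#' @export
anderson_darling <- function(values) {
  if (length(values) < 8L) stop("need n >= 8", call. = FALSE)
  if (stats::sd(values) == 0) stop("constant sample", call. = FALSE)
  res <- nortest::ad.test(values)
  list(A2 = unname(res$statistic), p = res$p.value)
}

#' Paired-sample t-test on metric differences
#'
#' `t = (Dbar - mu_D) / (S_D / sqrt(N))` with hypothesized mean difference
#' `mu_D = 0` and a two-sided p-value from the t distribution with N - 1
#' degrees of freedom. When every difference is zero the statistic is
#' reported as 0 with p = 1; a zero-variance, non-zero mean difference gives
#' an infinite statistic with p = 0.
#'
#' @param a,b Paired numeric vectors, or `b = NULL` to treat `a` as the
#'   differences directly.
#' @return A list of class `paired_test`: `mean_diff`, `sd_diff`, `n`, `t`,
#'   `p_value`, `significant` (p <= 0.05).
#' @export
paired_t <- function(a, b = NULL) {
  d <- if (is.null(b)) as.numeric(a) else as.numeric(a) - as.numeric(b)
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1L)
  }
  structure(list(mean_diff = m, sd_diff = s, n = n, t = t, p_value = p,
                 significant = p <= 0.05),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired t-test: mean diff %.4g, t = %.4g (n = %d), p = %.4g%s\n",
              x$mean_diff, x$t, x$n, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}
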