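# Independent brute-force oracles, written directly from the definitions and
# sharing no code with the package internals.

# FRNN prediction by direct enumeration over neighbours and classes.
oracle_frnn_predict <- function(X, labels, a_min, a_max, y, k) {
  n <- nrow(X)
  d <- ncol(X)
  sims <- numeric(n)
  for (i in seq_len(n)) {
    s <- 1
    for (j in seq_len(d)) {
      rng <- a_max[j] - a_min[j]
      yv <- min(max(y[j], a_min[j]), a_max[j])
      xv <- min(max(X[i, j], a_min[j]), a_max[j])
      sij <- if (rng <= 0) 1 else 1 - abs(xv - yv) / rng
      if (sij < s) s <- sij
    }
    sims[i] <- s
  }
  ord <- order(-sims, seq_len(n))
  take <- ord[seq_len(min(k, n))]
  classes <- sort(unique(labels))
  lower <- upper <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    lo <- Inf
    up <- -Inf
    for (t in take) {
      memb <- if (labels[t] == cl) 1 else 0
      lo <- min(lo, max(1 - sims[t], memb))
      up <- max(up, min(sims[t], memb))
    }
    lower[cl] <- lo
    upper[cl] <- up
  }
  score <- (lower + upper) / 2
  pick <- order(-score, -upper, classes)[1]
  list(predicted = classes[pick], lower = lower, upper = upper)
}

# Least-used deletion target by lexicographic (counter, insertion_index) argmin.
oracle_delete_target <- function(counters, insertion_indices) {
  best <- 1L
  for (i in seq_along(counters)) {
    if (counters[i] < counters[best] ||
        (counters[i] == counters[best] &&
         insertion_indices[i] < insertion_indices[best])) {
      best <- i
    }
  }
  best
}

# Majority-vote KNN by direct counting; ties fall back to the nearest object.
oracle_knn_vote <- function(X, labels, y, k) {
  d2 <- apply(X, 1L, function(r) sum((r - y)^2))
  ord <- order(d2, seq_len(nrow(X)))
  labs <- labels[ord[seq_len(min(k, nrow(X)))]]
  counts <- table(labs)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) == 1L) winners else labs[1L]
}

# Mann-Whitney AUC by pair counting with half credit for ties.
oracle_auc_pairs <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Small random labelled pool as a tibble.
random_pool_table <- function(n, d, n_classes, seed) {
  set.seed(seed)
  n <- max(n, n_classes)
  tb <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * d), n, d)))
  names(tb) <- paste0("f", seq_len(d))
  tb$class <- sample(letters[seq_len(n_classes)], n, replace = TRUE)
  # guarantee every class appears at least once
  tb$class[seq_len(n_classes)] <- letters[seq_len(n_classes)]
  tb
}
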