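#' Inverse ten-fold split for streaming evaluation
#'
#' Partitions the table into `folds` stratified folds; each fold in turn
#' serves as the small (about 10%) initial training pool while the other
#' folds, in arrival (row) order, form the test stream. This inverts the
#' usual cross-validation proportions: in an incremental setting the model
#' keeps learning from the stream, so the enrolment set can be small.
#'
#' @param table Data frame with a class column; row order is the arrival
#'   order of the stream.
#' @param seed Integer seed controlling the stratified assignment.
#' @param folds Number of folds (default 10).
#' @param class_col Class column name (default `"class"`).
#' @return A list of length `folds`; each element has `train_ids` and
#'   `stream_ids` (row indices, stream in arrival order).
#' @export
inverse_tenfold_split <- function(table, seed, folds = 10, class_col = "class") {
  labels <- as.character(table[[class_col]])
  counts <- table(labels)
  if (any(counts < folds)) {
    stop("every class needs at least ", folds, " objects", call. = FALSE)
  }
  n <- nrow(table)
  assign <- integer(n)
  set.seed(as.integer(seed))
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    fl <- rep_len(seq_len(folds), length(idx))
    assign[idx] <- sample(fl)
  }
  lapply(seq_len(folds), function(f) {
    list(train_ids = which(assign == f),
         stream_ids = which(assign != f))
  })
}

#' Run one classifier over a data stream
#'
#' Initialises the training pool from `train`, then classifies each `stream`
#' row in order and applies the configured incremental update. True labels
#' are consumed only for metric computation, except under the actual-class
#' strategy where they also drive insertions.
#'
#' @param train,stream Data frames with identical feature columns and a
#'   class column.
#' @param classifier `"frnn"` or `"knn"`.
#' @param config An [update_config()] (for FRNN) or [knn_config()] (for
#'   KNN).
#' @param positive Positive-class label for scores and metrics (default
#'   `"client"`).
#' @param class_col Class column name.
#' @param audit If `TRUE`, keep the per-object insertion-context audit
#'   records (probability strategy only).
#' @return A `stream_report`: list with `records` (tibble: truth, predicted,
#'   score), `metrics` (one-row tibble), `initial_size`, `final_size`,
#'   `insertions`, `deletions`, `max_size_after_update`, `classifier`,
#'   `strategy`, and optionally `audit`.
#' @export
stream_run <- function(train, stream, classifier = c("frnn", "knn"),
                       config = update_config(), positive = "client",
                       class_col = "class", audit = FALSE) {
  classifier <- match.arg(classifier)
  pool <- frnn_pool(train, class_col = class_col)
  feat_cols <- pool$feature_names
  Xs <- as.matrix(stream[feat_cols])
  truth <- as.character(stream[[class_col]])
  n <- nrow(Xs)
  predicted <- character(n)
  score <- numeric(n)
  insertions <- 0L
  deletions <- 0L
  max_size <- pool_size(pool)
  init_size <- pool_size(pool)
  audit_rows <- if (audit) vector("list", n) else NULL

  for (i in seq_len(n)) {
    y <- Xs[i, ]
    if (classifier == "frnn") {
      k <- config$k
      npool <- pool_size(pool)
      nn <- .neighbour_scan(pool, y, k + 1L)
      top_k <- nn$ids[seq_len(min(k, length(nn$ids)))]
      sc <- .score_from_neighbours(pool, nn$sims[seq_along(top_k)],
                                   pool$labels[top_k])
      predicted[i] <- sc$predicted
      score[i] <- if (positive %in% sc$classes) {
        sc$score[match(positive, sc$classes)]
      } else 0
      if (config$strategy == "probability") {
        if (npool < 2L) {
          pool <- pool_insert(pool, y, sc$predicted)
          insertions <- insertions + 1L
        } else {
          D <- relative_difference(nn$sims[1L], nn$sims[2L])
          thr <- insertion_threshold(nn$sims)
          probs <- class_probabilities(pool, top_k)
          best <- .best_prob_class(probs, sc$predicted)
          pool <- increment_usage(pool, top_k)
          ins <- decide_insertion(D, thr, sc$predicted, best)
          if (ins) {
            pool <- pool_insert(pool, y, sc$predicted)
            insertions <- insertions + 1L
          }
          win <- .apply_window(pool, config$window_size)
          pool <- win$pool
          deletions <- deletions + length(win$deleted)
          if (audit) {
            audit_rows[[i]] <- tibble::tibble(
              step = i, D = D, threshold = thr, predicted = sc$predicted,
              best_prob_class = best, inserted = ins,
              n_deleted = length(win$deleted))
          }
        }
      } else if (config$strategy == "actual_class") {
        pool <- increment_usage(pool, top_k)
        if (!identical(sc$predicted, truth[i])) {
          pool <- pool_insert(pool, y, truth[i])
          insertions <- insertions + 1L
        }
        win <- .apply_window(pool, config$window_size)
        pool <- win$pool
        deletions <- deletions + length(win$deleted)
      } # strategy "none": static pool
    } else {
      res <- knn_predict(pool, y, k = config$k, positive = positive)
      predicted[i] <- res$predicted
      score[i] <- res$score
      lab <- if (config$insert_label_mode == "actual") truth[i] else res$predicted
      before <- pool_size(pool)
      pool <- apply_fifo_update(pool, y, lab, config)
      insertions <- insertions + 1L
      deletions <- deletions + (before + 1L - pool_size(pool))
    }
    max_size <- max(max_size, pool_size(pool))
  }

  records <- tibble::tibble(truth = truth, predicted = predicted, score = score)
  strategy <- if (classifier == "knn") "fifo_knn" else config$strategy
  structure(list(
    records = records,
    metrics = compute_metrics(records, positive = positive),
    initial_size = init_size,
    final_size = pool_size(pool),
    insertions = insertions,
    deletions = deletions,
    max_size_after_update = max_size,
    classifier = classifier,
    strategy = strategy,
    final_pool = pool,
    audit = if (audit) dplyr::bind_rows(audit_rows) else NULL
  ), class = "stream_report")
}

# FRNN lower/upper approximations from an already-retrieved neighbour set.
.score_from_neighbours <- function(pool, sims, labs) {
  cls <- pool$class_set
  nl <- length(cls)
  lower <- numeric(nl); upper <- numeric(nl)
  for (j in seq_len(nl)) {
    memb <- as.numeric(labs == cls[j])
    lower[j] <- min(pmax(1 - sims, memb))
    upper[j] <- max(pmin(sims, memb))
  }
  sc <- (lower + upper) / 2
  ord <- order(-sc, -upper, cls)
  list(classes = cls, lower = lower, upper = upper, score = sc,
       predicted = cls[ord[1L]])
}

#' @export
print.stream_report <- function(x, ...) {
  m <- x$metrics
  cat("<stream_report> ", x$classifier, "/", x$strategy, ": ",
      nrow(x$records), " objects streamed; pool ", x$initial_size, " -> ",
      x$final_size, "\n", sep = "")
  cat(sprintf("  AUC %.4f  acc %.4f  recall %.4f  precision %.4f  F %.4f\n",
              m$auc, m$accuracy, m$recall, m$precision, m$f_measure))
  invisible(x)
}

#' Compare incremental update strategies on a feature stream
#'
#' Runs every configuration over the same inverse ten-fold splits and stream
#' orders (per seed the rows are shuffled once and shared by all
#' configurations, so per-fold metrics are paired), aggregates the per-run
#' metrics, and applies an Anderson-Darling normality check plus a paired
#' t-test to every configuration pair and metric.
#'
#' @param table Feature table with a class column.
#' @param configs Named list; each element is an [update_config()] or
#'   [knn_config()].
#' @param seeds Integer vector of stream-order seeds.
#' @param folds Which folds of each split to run (default `1:10`; use a
#'   subset to trade replication for speed).
#' @param n_folds Number of folds in each split (default 10).
#' @param positive Positive-class label.
#' @param class_col Class column name.
#' @return A `strategy_comparison`: list with `runs` (per seed x fold x
#'   config metrics), `summary` (mean metrics per config), and `tests`
#'   (pairwise AD + paired-t results per metric).
#' @export
compare_strategies <- function(table, configs, seeds, folds = 1:10,
                               n_folds = 10, positive = "client",
                               class_col = "class") {
  stopifnot(length(configs) >= 2L, !is.null(names(configs)))
  runs <- list()
  for (seed in seeds) {
    set.seed(as.integer(seed))
    ord <- sample(nrow(table))
    tbl <- table[ord, , drop = FALSE]
    splits <- inverse_tenfold_split(tbl, seed = seed, folds = n_folds,
                                    class_col = class_col)
    for (f in folds) {
      sp <- splits[[f]]
      train <- tbl[sp$train_ids, , drop = FALSE]
      stream <- tbl[sp$stream_ids, , drop = FALSE]
      for (cn in names(configs)) {
        cfg <- configs[[cn]]
        cls <- if (inherits(cfg, "knn_config")) "knn" else "frnn"
        rep <- stream_run(train, stream, classifier = cls, config = cfg,
                          positive = positive, class_col = class_col)
        runs[[length(runs) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(seed = seed, fold = f, config = cn), rep$metrics)
      }
    }
  }
  runs <- dplyr::bind_rows(runs)
  metric_cols <- c("auc", "accuracy", "recall", "precision", "f_measure")
  summary <- runs |>
    dplyr::group_by(.data$config) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols), mean),
                     .groups = "drop")
  cfg_names <- names(configs)
  tests <- list()
  for (i in seq_along(cfg_names)) for (j in seq_along(cfg_names)) {
    if (i >= j) next
    a <- runs[runs$config == cfg_names[i], ]
    b <- runs[runs$config == cfg_names[j], ]
    key <- paste(a$seed, a$fold)
    b <- b[match(key, paste(b$seed, b$fold)), ]
    for (m in metric_cols) {
      d <- a[[m]] - b[[m]]
      ad_p <- if (length(d) >= 8L && stats::sd(d) > 0) {
        anderson_darling(d)$p
      } else NA_real_
      tt <- paired_t(d)
      tests[[length(tests) + 1L]] <- tibble::tibble(
        config_a = cfg_names[i], config_b = cfg_names[j], metric = m,
        mean_diff = tt$mean_diff, t = tt$t, p_value = tt$p_value,
        significant = tt$significant, ad_normality_p = ad_p)
    }
  }
  structure(list(runs = runs, summary = summary,
                 tests = dplyr::bind_rows(tests)),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison> ", nrow(x$runs), " runs, ",
      length(unique(x$runs$config)), " configurations\n", sep = "")
  print(x$summary)
  invisible(x)
}
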