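small_stream_table <- function(seed = 1) {
  tbl <- simulate_feature_stream(n_subjects = 5, n_per_subject = 30,
                                 n_features = 4, client_subject = 1,
                                 seed = seed)
  tbl$subject <- NULL
  tbl
}

test_that("inverse folds partition the data with stratified small pools", {
  tbl <- small_stream_table()
  sp <- inverse_tenfold_split(tbl, seed = 9)
  expect_length(sp, 10L)
  train_union <- sort(unlist(lapply(sp, `[[`, "train_ids")))
  expect_equal(train_union, seq_len(nrow(tbl)))  # each row trains exactly once
  for (f in sp) {
    expect_setequal(c(f$train_ids, f$stream_ids), seq_len(nrow(tbl)))
    expect_gte(sum(tbl$class[f$train_ids] == "client"), 1L)
    expect_equal(f$stream_ids, sort(f$stream_ids))  # arrival order
  }
  expect_identical(inverse_tenfold_split(tbl, seed = 9), sp)

  few <- tbl[c(which(tbl$class == "client")[1:5],
               which(tbl$class == "impostor")), ]
  expect_error(inverse_tenfold_split(few, seed = 1), "at least 10")
})

test_that("a static-pool run leaves the pool untouched", {
  tbl <- small_stream_table()
  r <- stream_run(tbl[1:30, ], tbl[31:80, ], "frnn",
                  update_config(strategy = "none"))
  expect_equal(r$final_size, 30L)
  expect_equal(r$insertions, 0L)
  expect_equal(r$deletions, 0L)
  expect_identical(r$final_pool$counter, rep(1L, 30))
})

test_that("pool bookkeeping identity holds for an unwindowed probability run", {
  tbl <- small_stream_table(2)
  r <- stream_run(tbl[1:30, ], tbl[31:120, ], "frnn",
                  update_config(window_size = 0), audit = TRUE)
  expect_equal(r$final_size, 30L + r$insertions)
  expect_equal(r$deletions, 0L)
  expect_equal(sum(r$audit$inserted), r$insertions)
})

test_that("streamed probability updates replay the public single-step API", {
  tbl <- small_stream_table(3)
  train <- tbl[1:25, ]
  stream <- tbl[26:65, ]
  cfg <- update_config(k = 3, window_size = 28)
  r <- stream_run(train, stream, "frnn", cfg)

  pool <- frnn_pool(train)
  preds <- character(nrow(stream))
  for (i in seq_len(nrow(stream))) {
    y <- as.numeric(stream[i, paste0("f", 1:4)])
    sc <- frnn_predict(pool, y, k = cfg$k)
    preds[i] <- attr(sc, "predicted")
    pool <- apply_probability_update(pool, y, sc, cfg)$pool
  }
  expect_identical(r$records$predicted, preds)
  expect_equal(r$final_pool$X, pool$X, ignore_attr = TRUE)
  expect_identical(r$final_pool$counter, pool$counter)
})

test_that("windowed runs never exceed the cap after an update", {
  tbl <- small_stream_table(4)
  for (cl in c("frnn", "knn")) {
    cfg <- if (cl == "frnn") update_config(k = 3, window_size = 27) else
      knn_config(k = 3, window_size = 27)
    r <- stream_run(tbl[1:30, ], tbl[31:150, ], cl, cfg)
    expect_lte(r$final_size, max(30L, 27L))
    expect_lte(r$max_size_after_update, max(30L, 27L) + 1L)  # transient only
  }
})

test_that("replays with the same inputs are byte-identical", {
  tbl <- small_stream_table(5)
  r1 <- stream_run(tbl[1:30, ], tbl[31:100, ], "frnn", update_config())
  r2 <- stream_run(tbl[1:30, ], tbl[31:100, ], "frnn", update_config())
  expect_identical(r1$records, r2$records)
  expect_identical(r1$metrics, r2$metrics)
})

test_that("strategy comparison is shaped, paired and self-consistent", {
  tbl <- small_stream_table(6)
  cmp <- compare_strategies(
    tbl,
    configs = list(prob = update_config(k = 3),
                   prob2 = update_config(k = 3),
                   fifo = knn_config(k = 3)),
    seeds = c(11, 12), folds = 1)
  expect_equal(nrow(cmp$runs), 2 * 1 * 3)
  expect_equal(nrow(cmp$summary), 3L)
  expect_equal(nrow(cmp$tests), choose(3, 2) * 5)  # pairs x metrics

  # identical configurations differ by exactly nothing
  ident <- cmp$tests[cmp$tests$config_a == "prob" & cmp$tests$config_b == "prob2", ]
  expect_true(all(ident$mean_diff == 0))
  expect_true(all(ident$p_value == 1))

  cmp2 <- compare_strategies(
    tbl, configs = list(prob = update_config(k = 3), fifo = knn_config(k = 3)),
    seeds = c(11, 12), folds = 1)
  expect_identical(
    cmp$runs[cmp$runs$config == "prob", ],
    cmp2$runs[cmp2$runs$config == "prob", ])
})

test_that("tidy and glance expose records and summaries", {
  tbl <- small_stream_table(7)
  r <- stream_run(tbl[1:30, ], tbl[31:60, ], "frnn", update_config())
  expect_identical(tidy(r), r$records)
  g <- glance(r)
  expect_equal(g$strategy, "probability")
  expect_equal(g$auc, r$metrics$auc)
  tt <- tidy(paired_t(c(2, 0, 1, 3, -1)))
  expect_equal(tt$statistic, sqrt(2))
})
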