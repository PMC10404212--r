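test_that("relative difference and threshold match hand-computed values", {
  expect_equal(relative_difference(0.8, 0.8), 0)
  expect_equal(relative_difference(1.0, 0.5), 0.5 / 0.75)
  expect_equal(relative_difference(0.6, 0.0), 2.0)
  expect_equal(relative_difference(0, 0), 0)
  expect_error(relative_difference(0.3, 0.6), "descending")

  expect_equal(insertion_threshold(c(1.0, 0.5)), 0.5 * (0.5 / 0.75))
  expect_equal(insertion_threshold(c(0.7, 0.7, 0.7)), 0)
  expect_equal(insertion_threshold(c(1.0, 0.8, 0.6)),
               0.5 * (0.2 / 0.9 + 0.2 / 0.7))
  expect_error(insertion_threshold(0.9), "at least two")
})

test_that("class probabilities follow the counter-ratio formula", {
  tb <- tibble::tibble(f1 = c(0, 0.1, 5, 6), class = c("a", "a", "b", "b"))
  p <- frnn_pool(tb)
  # neighbours: both class a with counters 1, 1; pool totals a = 2, b = 2
  pr <- class_probabilities(p, c(1L, 2L))
  expect_equal(unname(pr["a"]), (2 / 2) / 2)
  expect_equal(unname(pr["b"]), 0)

  # split neighbours with equal counters and equal pool totals: symmetric
  pr2 <- class_probabilities(p, c(1L, 3L))
  expect_equal(unname(pr2["a"]), unname(pr2["b"]))

  only <- frnn_pool(tibble::tibble(f1 = c(0, 1), class = c("a", "a")))
  pr3 <- class_probabilities(only, 1L)
  expect_equal(names(which.max(pr3)), "a")
})

test_that("insertion decision truth table has exactly the two prescribed cells", {
  expect_true(decide_insertion(0.8, 0.3, "a", "b"))    # large gap, disagree
  expect_true(decide_insertion(0.1, 0.3, "a", "a"))    # small gap, agree
  expect_false(decide_insertion(0.8, 0.3, "a", "a"))
  expect_false(decide_insertion(0.1, 0.3, "a", "b"))
  expect_false(decide_insertion(0.3, 0.3, "a", "a"))   # exact tie: no insert
  expect_false(decide_insertion(0.3, 0.3, "a", "b"))
  cells <- c(decide_insertion(1, 0.5, "a", "b"), decide_insertion(1, 0.5, "a", "a"),
             decide_insertion(0.1, 0.5, "a", "b"), decide_insertion(0.1, 0.5, "a", "a"))
  expect_equal(sum(cells), 2L)
})

test_that("probability update composes retrieval, counters, insertion, window", {
  tb <- random_pool_table(12, 3, 2, seed = 11)
  p <- frnn_pool(tb)
  y <- rnorm(3)
  cfg <- update_config(k = 5, window_size = 0)
  res <- apply_probability_update(p, y, config = cfg)
  ctx <- res$context
  expect_equal(sum(res$pool$counter) - sum(p$counter),
               5L + as.integer(ctx$inserted))
  expect_equal(pool_size(res$pool), pool_size(p) + as.integer(ctx$inserted))
  expect_equal(ctx$n_deleted, 0L)  # window 0: never deletes

  # at a cap, a firing insertion still leaves the pool at the cap
  cfg10 <- update_config(k = 3, window_size = 10)
  p10 <- frnn_pool(random_pool_table(10, 2, 2, seed = 12))
  res10 <- apply_probability_update(p10, rnorm(2), config = cfg10)
  expect_lte(pool_size(res10$pool), 10L)
  if (res10$context$inserted) expect_equal(pool_size(res10$pool), 10L)

  # deterministic: same pool, same object, same result
  res2 <- apply_probability_update(p, y, config = cfg)
  expect_identical(res$context, res2$context)
  expect_identical(res$pool$X, res2$pool$X)
})

test_that("cold-start pools insert unconditionally", {
  p <- frnn_pool(tibble::tibble(f1 = 0, f2 = 0, class = "a"))
  res <- apply_probability_update(p, c(1, 1), config = update_config())
  expect_true(res$context$inserted)
  expect_equal(pool_size(res$pool), 2L)
})

test_that("actual-class updates insert only on misclassification", {
  tb <- tibble::tibble(f1 = c(0, 0.1, 1), class = c("a", "a", "b"))
  p <- frnn_pool(tb)
  cfg <- update_config(k = 2, strategy = "actual_class")
  same <- apply_actual_class_update(p, 0.05, "a", "a", cfg)
  expect_equal(pool_size(same), 3L)
  diff <- apply_actual_class_update(p, 0.05, "a", "b", cfg)
  expect_equal(pool_size(diff), 4L)
  expect_equal(diff$labels[4], "b")  # stored under the actual label

  # cap reached and misclassified: least-used object evicted
  cfg_cap <- update_config(k = 2, window_size = 3, strategy = "actual_class")
  capped <- apply_actual_class_update(p, 0.05, "a", "b", cfg_cap)
  expect_equal(pool_size(capped), 3L)
})

test_that("with equal counters windowed eviction reduces to FIFO order", {
  p <- frnn_pool(random_pool_table(6, 2, 2, seed = 21))
  out <- incfrnn:::.apply_window(p, 3L)
  expect_equal(out$deleted, 0:2)
  expect_equal(out$pool$insertion_index, 3:5)
})

test_that("probability updates cannot read the actual label", {
  expect_false("actual" %in% names(formals(apply_probability_update)))
})
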