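test_that("subject parameters are reproducible and subject-specific", {
  a <- sample_subject(1)
  b <- sample_subject(1)
  expect_identical(a, b)
  c <- sample_subject(2)
  expect_false(isTRUE(all.equal(a$alpha_peak_hz, c$alpha_peak_hz)))
  peaks <- vapply(1:45, function(s) sample_subject(s)$alpha_peak_hz, numeric(1))
  expect_equal(length(unique(peaks)), 45L)
  expect_true(all(peaks >= 8 & peaks <= 13))
  expect_true(isSymmetric(a$coupling))
  expect_equal(unname(diag(a$coupling)), rep(1, 5))
})

test_that("sessions are reproducible with the stated trial structure", {
  sp <- sample_subject(4)
  s1 <- simulate_session(sp, "quiet", n_trials = 20, seed = 9)
  s2 <- simulate_session(sp, "quiet", n_trials = 20, seed = 9)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_equal(length(s1$recording$onsets), 20L)
  expect_equal(diff(s1$recording$onsets)[1], round(2.5 * 512))
  expect_equal(sum(s1$trial_labels == "target"), 8L)  # 40% targets

  full <- simulate_session(sp, "quiet", n_trials = 150, seed = 9)
  expect_equal(sum(full$trial_labels == "target"), 60L)
  expect_equal(sum(full$trial_labels == "nontarget"), 90L)
})

test_that("strong phase locking drives WPS toward 1 on target trials", {
  sp <- sample_subject(5)
  sp$phase_lock_kappa <- 1e6
  sp$artifact_rate <- 0
  ss <- simulate_session(sp, "quiet", n_trials = 30, seed = 11)
  rec <- fir_bandpass(ss$recording, 8, 13)
  ep <- segment(rec, 1.0)
  tgt <- which(ss$trial_labels == "target")
  ep$data <- ep$data[tgt, , , drop = FALSE]
  ep$kept_trial_ids <- tgt
  w <- wps(ep, "OZ", c(8, 13))
  expect_gt(w$gamma, 0.95)
})

test_that("unit coupling with shared sources drives coherence up", {
  sp <- sample_subject(6)
  sp$artifact_rate <- 0
  sp$coupling[, ] <- 0
  diag(sp$coupling) <- 1
  sp$coupling["O1", "OZ"] <- sp$coupling["OZ", "O1"] <- 0.999
  ss <- simulate_session(sp, "quiet", n_trials = 30, seed = 12)
  ep <- segment(fir_bandpass(ss$recording, 8, 13), 1.0)
  co <- coherence(ep, "O1", "OZ", c(8, 13))
  expect_gt(co$band_mean, 0.9)

  sp$coupling["O1", "OZ"] <- sp$coupling["OZ", "O1"] <- 0
  ss0 <- simulate_session(sp, "quiet", n_trials = 30, seed = 12)
  ep0 <- segment(fir_bandpass(ss0$recording, 8, 13), 1.0)
  co0 <- coherence(ep0, "O1", "OZ", c(8, 13))
  expect_lt(co0$band_mean, co$band_mean)
})

test_that("artefact trials appear at a binomially plausible rate", {
  sp <- sample_subject(7)
  sp$phase_lock_kappa <- 2
  sp$artifact_rate <- 0.1
  ss <- simulate_session(sp, "quiet", n_trials = 150, seed = 13)
  ep <- segment(ss$recording, 1.0)
  peak <- apply(abs(ep$data), 1, max)
  n_art <- sum(peak > 100)
  expect_gte(n_art, 1L)
  expect_lte(n_art, qbinom(0.9999, 150, 0.1) + 20L)  # loose upper sanity bound
})

test_that("feature streams have the declared size, imbalance and drift", {
  tbl <- simulate_feature_stream(seed = 31)
  expect_equal(nrow(tbl), 6750L)
  expect_equal(sum(tbl$class == "client"), 150L)
  expect_equal(ncol(tbl), 12L + 2L)
  expect_identical(simulate_feature_stream(seed = 31), tbl)

  drift0 <- simulate_feature_stream(n_subjects = 4, n_per_subject = 200,
                                    n_features = 3, drift = 0,
                                    feature_scales = rep(1, 3), seed = 32)
  cli <- drift0[drift0$class == "client", ]
  first <- colMeans(cli[1:50, paste0("f", 1:3)])
  last <- colMeans(cli[151:200, paste0("f", 1:3)])
  expect_lt(sqrt(sum((first - last)^2)), 0.5)  # no systematic displacement

  drifted <- simulate_feature_stream(n_subjects = 4, n_per_subject = 200,
                                     n_features = 3, drift = 3,
                                     feature_scales = rep(1, 3), seed = 32)
  cli2 <- drifted[drifted$class == "client", ]
  gap <- sqrt(sum((colMeans(cli2[151:200, paste0("f", 1:3)]) -
                     colMeans(cli2[1:50, paste0("f", 1:3)]))^2))
  expect_gt(gap, 1)
})
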