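fs <- 512

sine_rec <- function(freq, secs = 4, amp = 1, nch = 1) {
  t <- (0:(secs * fs - 1)) / fs
  x <- matrix(rep(amp * sin(2 * pi * freq * t), nch), nrow = nch, byrow = TRUE)
  eeg_recording(x, fs = fs, channel_names = paste0("C", seq_len(nch)),
                onsets = integer(0))
}

test_that("FIR bandpass passes the band, rejects stopband and DC", {
  rec10 <- sine_rec(10)
  f10 <- fir_bandpass(rec10, 8, 13)
  mid <- (fs + 1):(3 * fs)  # interior, clear of transients
  expect_gt(max(abs(f10$samples[1, mid])), 0.95)
  expect_lt(max(abs(f10$samples[1, mid])) , 1.05)

  f40 <- fir_bandpass(sine_rec(40), 8, 13)
  expect_lt(max(abs(f40$samples[1, mid])), 0.05)

  dc <- eeg_recording(matrix(5, 1, 4 * fs), fs = fs, channel_names = "C1")
  fdc <- fir_bandpass(dc, 8, 13)
  expect_lt(max(abs(fdc$samples[1, mid])), 0.05)

  expect_error(fir_bandpass(rec10, 13, 8), "invalid band")
  expect_error(fir_bandpass(rec10, 8, 300), "invalid band")
  expect_error(fir_bandpass(rec10, 8, 13, taps = 512), "odd")
})

test_that("group delay is compensated: filtered in-band sine stays aligned", {
  rec <- sine_rec(10)
  f <- fir_bandpass(rec, 8, 13)
  mid <- (fs + 1):(3 * fs)
  expect_gt(cor(rec$samples[1, mid], f$samples[1, mid]), 0.999)
  expect_equal(ncol(f$samples), ncol(rec$samples))
})

test_that("segmentation yields one fixed-length epoch per viable onset", {
  x <- matrix(rnorm(2 * 10 * fs), nrow = 2)
  onsets <- seq(1, 9 * fs, by = fs %/% 2)
  rec <- eeg_recording(x, fs = fs, channel_names = c("A", "B"), onsets = onsets)
  ep <- segment(rec, 1.0)
  expect_equal(dim(ep$data), c(length(onsets), 2, fs))

  # an onset half a second before the end cannot host a 1 s epoch
  rec2 <- eeg_recording(x, fs = fs, channel_names = c("A", "B"),
                        onsets = c(onsets, 10 * fs - fs %/% 2))
  expect_warning(ep2 <- segment(rec2, 1.0), "dropped")
  expect_equal(dim(ep2$data)[1], length(onsets))
})

test_that("artefact rejection drops only trials strictly above threshold", {
  dat <- array(0, dim = c(3, 2, 100))
  dat[1, 1, 50] <- 150          # artefact
  dat[2, 2, 10] <- 100          # exactly at threshold: kept
  dat[3, , ] <- 50
  ep <- structure(list(data = dat, fs = fs, channel_names = c("A", "B"),
                       kept_trial_ids = 1:3), class = "epoch_set")
  out <- reject_artifacts(ep, 100)
  expect_equal(out$kept_trial_ids, 2:3)

  dat[, , ] <- 500
  ep_all <- structure(list(data = dat, fs = fs, channel_names = c("A", "B"),
                           kept_trial_ids = 1:3), class = "epoch_set")
  expect_error(reject_artifacts(ep_all, 100), "all trials")
})

test_that("periodogram matches closed forms and Parseval exactly", {
  N <- 256
  spec_dc <- psd(rep(3, N), fs)
  expect_equal(spec_dc$power[1], N * 9)
  expect_equal(max(spec_dc$power[-1]), 0, tolerance = 1e-9)

  # unit sine at an exact bin: two bins of N/4 each
  t <- 0:(N - 1)
  x <- sin(2 * pi * 8 * t / N)
  sp <- psd(x, fs)
  nz <- which(sp$power > 1e-6)
  expect_equal(nz, c(9L, N - 8L + 1L))
  expect_equal(unname(sp$power[nz]), rep(N / 4, 2))

  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(sample(16:512, 1))
    sp <- psd(x, fs)
    expect_equal(sum(sp$power), sum(x^2), tolerance = 1e-9)
  }
  expect_error(psd(numeric(0), fs), "short")
})

test_that("spectral shape features behave on constructed spectra", {
  N <- 512
  flat <- psd(rnorm(N), fs)
  flat$power[] <- 7            # flat spectrum by construction
  f <- psd_features(flat, c(8, 13))
  expect_equal(f$concavity, 0, tolerance = 1e-9)
  expect_equal(f$power_variance, 0)

  single <- flat
  single$power[] <- 0
  peak_bin <- which.min(abs(single$freq - 10))
  single$power[peak_bin] <- 100
  f1 <- psd_features(single, c(8, 13))
  expect_equal(f1$nondominant_ratio, 0)

  two <- single
  far_bin <- which.min(abs(two$freq - 12.5))   # > 2 Hz from the 10 Hz peak
  two$power[far_bin] <- 100
  f2 <- psd_features(two, c(8, 13))
  expect_equal(f2$nondominant_ratio, 0.5)

  expect_error(psd_features(flat, c(8, 400)), "Nyquist")
})

test_that("phase stability is 1 for identical trials and low for random phases", {
  t <- (0:(fs - 1)) / fs
  one <- sin(2 * pi * 10 * t)
  dat <- array(rep(one, each = 8), dim = c(8, 1, fs))
  for (m in 1:8) dat[m, 1, ] <- one
  ep <- structure(list(data = dat, fs = fs, channel_names = "OZ",
                       kept_trial_ids = 1:8), class = "epoch_set")
  w <- wps(ep, "OZ", c(8, 13))
  expect_equal(w$gamma, 1, tolerance = 1e-9)
  expect_true(all(w$gamma_t >= 0 & w$gamma_t <= 1))

  set.seed(4)
  M <- 120
  datr <- array(0, dim = c(M, 1, fs))
  for (m in 1:M) datr[m, 1, ] <- sin(2 * pi * 10 * t + runif(1, -pi, pi))
  epr <- structure(list(data = datr, fs = fs, channel_names = "OZ",
                        kept_trial_ids = 1:M), class = "epoch_set")
  wr <- wps(epr, "OZ", c(8, 13))
  expect_lt(wr$gamma, 0.25)
  expect_gte(wr$gamma, 0)
  expect_error(wps(structure(list(data = datr[1, , , drop = FALSE], fs = fs,
                                  channel_names = "OZ", kept_trial_ids = 1),
                             class = "epoch_set"), "OZ", c(8, 13)), "2 trials")
})

test_that("coherence is 1 for an exact scaled copy and low for independent noise", {
  set.seed(6)
  M <- 12
  dat <- array(0, dim = c(M, 2, 256))
  for (m in 1:M) {
    x <- rnorm(256)
    dat[m, 1, ] <- x
    dat[m, 2, ] <- 2 * x
  }
  ep <- structure(list(data = dat, fs = fs, channel_names = c("O1", "OZ"),
                       kept_trial_ids = 1:M), class = "epoch_set")
  co <- coherence(ep, "O1", "OZ", c(8, 13))
  expect_equal(co$band_mean, 1, tolerance = 1e-6)
  expect_true(all(co$cxy >= 0 & co$cxy <= 1, na.rm = TRUE))

  M2 <- 60
  dat2 <- array(rnorm(M2 * 2 * 256), dim = c(M2, 2, 256))
  ep2 <- structure(list(data = dat2, fs = fs, channel_names = c("O1", "OZ"),
                        kept_trial_ids = 1:M2), class = "epoch_set")
  co2 <- coherence(ep2, "O1", "OZ", c(8, 13))
  expect_lt(co2$band_mean, 0.3)
  expect_error(coherence(ep, "O1", "XX", c(8, 13)), "unknown channel")
})

test_that("descriptor grid emits the expected named feature set", {
  sp <- sample_subject(3)
  ss <- simulate_session(sp, "quiet", n_trials = 8, seed = 5)
  d <- session_descriptor(ss, block = 4)
  feat <- setdiff(names(d), c("trial", "class"))
  expect_equal(length(feat), 5 * 2 * 3 + 5 * 2 + 2 * 2)  # 44
  expect_true(all(grepl("^(psd|wps|coh)_", feat)))
  expect_true(all(d[[paste0("wps_OZ_alpha")]] >= 0 & d[["wps_OZ_alpha"]] <= 1))

  # the selected descriptor of the field (all PSD + WPS, two occipital
  # coherences) is expressible as a named column selection
  subset12 <- c("wps_T5_alpha", "wps_T6_alpha", "wps_O1_alpha", "wps_OZ_alpha",
                "wps_O2_alpha", "psd_T5_alpha_concavity", "psd_OZ_alpha_nondom",
                "psd_O2_alpha_powervar", "psd_O1_beta_concavity",
                "wps_OZ_beta", "coh_O1_OZ_alpha", "coh_OZ_O2_alpha")
  expect_true(all(subset12 %in% feat))

  # no coherence columns without pairs
  rec <- ss$recording
  eb <- list(alpha = segment(fir_bandpass(rec, 8, 13), 1))
  d2 <- build_descriptor(eb, bands = list(alpha = c(8, 13)), pairs = list())
  expect_false(any(grepl("^coh_", names(d2))))
  expect_error(build_descriptor(eb, bands = list(alpha = c(8, 13)),
                                channels = "ZZ"), "unknown channel")
})

test_that("filter-then-segment equals segment-then-filter away from edges", {
  set.seed(8)
  x <- matrix(rnorm(1 * 6 * fs), nrow = 1)
  on <- c(2 * fs, 4 * fs)
  rec <- eeg_recording(x, fs = fs, channel_names = "O1", onsets = on)
  a <- segment(fir_bandpass(rec, 8, 13), 1.0)
  # filter each whole-epoch window cut with generous context, then trim
  for (i in seq_along(on)) {
    ctx <- (on[i] - fs):(on[i] + 2 * fs - 1)
    recw <- eeg_recording(x[, ctx, drop = FALSE], fs = fs,
                          channel_names = "O1", onsets = fs + 1L)
    b <- segment(fir_bandpass(recw, 8, 13), 1.0)
    interior <- 100:(fs - 100)
    expect_equal(a$data[i, 1, interior], b$data[1, 1, interior],
                 tolerance = 1e-6)
  }
})
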