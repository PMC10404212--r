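#' Sample subject-specific EEG parameters
#'
#' Draws one subject's generative parameters from documented distributions:
#' an individual alpha peak frequency uniform on 8-13 Hz (alpha peaks are a
#' stable individual trait), log-normal alpha/beta oscillation amplitudes, a
#' gamma-distributed stimulus phase-locking concentration (von Mises kappa),
#' a symmetric unit-diagonal inter-channel coupling matrix built from an
#' occipitally-weighted template with subject jitter, an artefact-trial rate
#' and a per-trial multiplicative band-power drift rate.
#'
#' @param seed Integer seed; the same seed reproduces the same subject.
#' @param channel_names Channel montage (default the five occipito-temporal
#'   electrodes).
#' @return A list of class `subject_params`.
#' @export
sample_subject <- function(seed,
                           channel_names = c("T5", "T6", "O1", "OZ", "O2")) {
  set.seed(as.integer(seed))
  nch <- length(channel_names)
  # template: strong O1-OZ / OZ-O2 coupling, weaker elsewhere
  tmpl <- matrix(0.2, nch, nch, dimnames = list(channel_names, channel_names))
  for (pr in list(c("O1", "OZ"), c("OZ", "O2"))) {
    if (all(pr %in% channel_names)) {
      tmpl[pr[1], pr[2]] <- tmpl[pr[2], pr[1]] <- 0.7
    }
  }
  jit <- matrix(runif(nch * nch, -0.15, 0.15), nch)
  jit <- (jit + t(jit)) / 2
  coupling <- pmin(pmax(tmpl + jit, 0), 1)
  diag(coupling) <- 1
  structure(list(
    alpha_peak_hz = runif(1, 8, 13),
    alpha_power = rlnorm(1, log(12), 0.3),
    beta_power = rlnorm(1, log(6), 0.3),
    beta_freq_hz = runif(1, 16, 26),
    phase_lock_kappa = rgamma(1, shape = 4, rate = 1),
    coupling = coupling,
    artifact_rate = runif(1, 0.01, 0.08),
    drift_rate = runif(1, 0, 0.002),
    channel_names = channel_names,
    seed = as.integer(seed)
  ), class = "subject_params")
}

# von Mises sampler (Best & Fisher rejection); near-degenerate kappa falls
# back to the wrapped-normal limit.
.rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(runif(n, -pi, pi))
  if (kappa > 1e4) return((mu + rnorm(n, 0, 1 / sqrt(kappa)) + pi) %% (2 * pi) - pi)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  (mu + out + pi) %% (2 * pi) - pi
}

# Nearest positive-definite correction for a correlation-like matrix:
# eigenvalues clipped at a small floor, unit diagonal restored.
.nearest_pd <- function(C, floor_ev = 1e-4) {
  e <- eigen(C, symmetric = TRUE)
  v <- pmax(e$values, floor_ev)
  M <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  (M + t(M)) / 2 + diag(1e-8, nrow(C))
}

# 1/f ("pink") noise via spectral shaping, sd-normalised.
.pink_noise <- function(n, sd = 1) {
  white <- rnorm(n)
  f <- stats::fft(white)
  k <- c(1, seq_len(n - 1))
  shape <- 1 / sqrt(pmin(k, n - k + 1))
  x <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

#' Simulate one EEG session
#'
#' Generates a multi-channel stimulus-paradigm session: `n_trials` trials of
#' 2.5 s each (1 s stimulus + 1.5 s inter-stimulus interval) at `fs` Hz,
#' with 40% target (password-image) and 60% non-target trials shuffled.
#' Each trial is pink noise plus a subject-specific alpha oscillation whose
#' phase at stimulus onset is von Mises concentrated (kappa) on target
#' trials and uniform otherwise, plus a beta oscillation whose amplitude
#' grows with the ambient-distraction condition, all mixed across channels
#' through the subject's coupling matrix. A fraction of trials receives a
#' >100 microvolt artefact excursion, and band amplitudes drift
#' multiplicatively across trials (nonstationarity).
#'
#' @param params A [sample_subject()] result.
#' @param condition `"quiet"`, `"low_distraction"`, or `"high_distraction"`
#'   (scales beta amplitude 0.6 / 1.0 / 1.4 and the noise floor).
#' @param n_trials Number of trials (default 150).
#' @param fs Sampling rate (default 512 Hz).
#' @param seed Integer seed.
#' @return A list of class `simulated_session`: `recording`
#'   (an [eeg_recording()]), `trial_labels` (`"target"`/`"nontarget"`),
#'   `condition`, `params`, `seed`.
#' @export
simulate_session <- function(params,
                             condition = c("quiet", "low_distraction",
                                           "high_distraction"),
                             n_trials = 150, fs = 512, seed = 1) {
  condition <- match.arg(condition)
  set.seed(as.integer(seed))
  nch <- length(params$channel_names)
  trial_len <- round(2.5 * fs)
  n_target <- round(0.4 * n_trials)
  labels <- sample(c(rep("target", n_target),
                     rep("nontarget", n_trials - n_target)))
  beta_gain <- c(quiet = 0.6, low_distraction = 1.0, high_distraction = 1.4)[condition]
  noise_sd <- c(quiet = 5, low_distraction = 6.5, high_distraction = 8)[condition]
  mix <- t(chol(.nearest_pd(params$coupling)))
  tt <- (0:(trial_len - 1)) / fs
  X <- matrix(0, nch, n_trials * trial_len)
  artifact <- rbinom(n_trials, 1, params$artifact_rate) == 1
  for (i in seq_len(n_trials)) {
    drift_mult <- (1 + params$drift_rate)^(i - 1)
    src <- matrix(0, nch, trial_len)
    alpha_phase0 <- if (labels[i] == "target") {
      .rvonmises(1, 0, params$phase_lock_kappa)
    } else runif(1, -pi, pi)
    for (ch in seq_len(nch)) {
      # small per-channel phase offset keeps channels coherent but not
      # identical before mixing
      a_ph <- alpha_phase0 + rnorm(1, 0, 0.2)
      b_ph <- runif(1, -pi, pi)
      src[ch, ] <- .pink_noise(trial_len, sd = noise_sd) +
        drift_mult * params$alpha_power *
          sin(2 * pi * params$alpha_peak_hz * tt + a_ph) +
        drift_mult * beta_gain * params$beta_power *
          sin(2 * pi * params$beta_freq_hz * tt + b_ph)
    }
    trial <- mix %*% src
    if (artifact[i]) {
      ch <- sample(nch, 1)
      at <- sample(trial_len - fs %/% 4, 1)
      blob <- 180 * sin(pi * seq(0, 1, length.out = fs %/% 4))
      trial[ch, at:(at + length(blob) - 1)] <- trial[ch, at:(at + length(blob) - 1)] + blob
    }
    X[, ((i - 1) * trial_len + 1):(i * trial_len)] <- trial
  }
  rec <- eeg_recording(X, fs = fs, channel_names = params$channel_names,
                       onsets = (0:(n_trials - 1)) * trial_len + 1L)
  structure(list(recording = rec, trial_labels = labels,
                 condition = condition, params = params,
                 seed = as.integer(seed)),
            class = "simulated_session")
}

#' Simulate a feature-space authentication stream
#'
#' Fast path that skips raw-signal synthesis: each subject's descriptor
#' vectors are drawn from a subject-specific multivariate normal (mean
#' spread 1 between subjects, within-subject spread `within_sd`), the
#' designated client's objects are labelled `"client"` and all others
#' `"impostor"` (1 : n_subjects - 1 imbalance), objects are interleaved in a
#' random arrival order, and every subject's mean drifts linearly along a
#' random unit direction by `drift` units over the whole stream
#' (nonstationarity).
#'
#' @param n_subjects Number of subjects (default 45).
#' @param n_per_subject Objects per subject (default 150; the default grid
#'   gives 6750 objects, 150 of them client).
#' @param n_features Feature dimension (default 12, the size of the selected
#'   descriptor subset).
#' @param client_subject Which subject is the enrolled client (default 1).
#' @param drift Total mean displacement over the stream, in between-subject
#'   spread units (default 0.5; 0 disables drift).
#' @param within_sd Within-subject feature standard deviation, in
#'   between-subject spread units (default 1.0, which puts single-run
#'   authentication difficulty in the realistic EEG-biometrics regime).
#' @param feature_scales Per-feature multiplicative scales applied to the
#'   finished features (default spans three orders of magnitude, emulating a
#'   descriptor that mixes unit-interval phase/coherence values with
#'   spectral-power features in squared microvolts; range-normalising
#'   classifiers are unaffected, scale-sensitive ones are not).
#' @param seed Integer seed.
#' @return A tibble: feature columns `f1..fd`, `class`, `subject`, rows in
#'   arrival order.
#' @export
simulate_feature_stream <- function(n_subjects = 45, n_per_subject = 150,
                                    n_features = 12, client_subject = 1,
                                    drift = 0.5, within_sd = 1.0,
                                    feature_scales = 10^seq(-1.5, 1.5,
                                                            length.out = n_features),
                                    seed = 1) {
  stopifnot(client_subject >= 1, client_subject <= n_subjects,
            length(feature_scales) == n_features)
  set.seed(as.integer(seed))
  mu <- matrix(rnorm(n_subjects * n_features), n_subjects, n_features)
  dirs <- matrix(rnorm(n_subjects * n_features), n_subjects, n_features)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sds <- matrix(within_sd * runif(n_subjects * n_features, 0.7, 1.3),
                n_subjects, n_features)
  n <- n_subjects * n_per_subject
  subject <- sample(rep(seq_len(n_subjects), n_per_subject))
  t_pos <- (seq_len(n) - 1) / max(1, n - 1)
  X <- matrix(0, n, n_features)
  for (i in seq_len(n)) {
    s <- subject[i]
    X[i, ] <- mu[s, ] + t_pos[i] * drift * dirs[s, ] +
      rnorm(n_features) * sds[s, ]
  }
  X <- sweep(X, 2L, feature_scales, `*`)
  colnames(X) <- paste0("f", seq_len(n_features))
  tb <- tibble::as_tibble(as.data.frame(X))
  tb$class <- ifelse(subject == client_subject, "client", "impostor")
  tb$subject <- subject
  tb
}

#' Descriptor table for a simulated session
#'
#' Convenience wrapper running the full signal path on one simulated
#' session: alpha and beta FIR bandpass filtering, trial segmentation,
#' artefact rejection (applied jointly so both bands keep the same trials),
#' and descriptor assembly.
#'
#' @param session A [simulate_session()] result.
#' @param bands Named band list (default alpha 8-13, beta 13-30 Hz).
#' @param epoch_len_s Epoch length from onset in seconds (default 1).
#' @param block Sliding-block length for WPS/coherence (default 10).
#' @param taps FIR length (default 513).
#' @return A descriptor tibble with a `trial` column and the trial labels in
#'   `class`.
#' @export
session_descriptor <- function(session,
                               bands = list(alpha = c(8, 13), beta = c(13, 30)),
                               epoch_len_s = 1, block = 10, taps = 513) {
  rec <- session$recording
  raw_epochs <- segment(rec, epoch_len_s)
  clean <- reject_artifacts(raw_epochs)
  keep <- clean$kept_trial_ids
  eb <- lapply(bands, function(b) {
    ep <- segment(fir_bandpass(rec, b[1], b[2], taps = taps), epoch_len_s)
    ep$data <- ep$data[keep, , , drop = FALSE]
    ep$kept_trial_ids <- keep
    ep
  })
  build_descriptor(eb, bands = bands, block = block,
                   labels = session$trial_labels)
}
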