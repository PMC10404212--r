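#' EEG recordings and epoch sets
#'
#' `eeg_recording()` wraps a channels-by-samples matrix (microvolts) with its
#' sampling rate, channel names and trial-onset sample indices. The default
#' montage is the five occipito-temporal electrodes used for visual/auditory
#' paradigms (T5, T6, O1, OZ, O2).
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param fs Sampling rate in Hz (default 512).
#' @param channel_names Character vector, one name per row.
#' @param onsets Strictly increasing 1-based sample indices of trial onsets.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs = 512,
                          channel_names = c("T5", "T6", "O1", "OZ", "O2"),
                          onsets = integer(0)) {
  samples <- as.matrix(samples)
  stopifnot(fs > 0, nrow(samples) == length(channel_names))
  onsets <- as.integer(onsets)
  if (length(onsets) > 1L && any(diff(onsets) <= 0L)) {
    stop("onsets must be strictly increasing", call. = FALSE)
  }
  if (length(onsets) > 0L && (min(onsets) < 1L || max(onsets) > ncol(samples))) {
    stop("onsets outside the recording", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 onsets = onsets),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", length(x$channel_names), " channels x ",
      ncol(x$samples), " samples @ ", x$fs, " Hz, ",
      length(x$onsets), " trial onsets\n", sep = "")
  invisible(x)
}

#' Linear-phase FIR bandpass filter
#'
#' Filters every channel with a windowed-sinc (Hamming) bandpass of odd
#' length, designed with [signal::fir1()]. The signal is reflection-padded at
#' both ends and the group delay of `(taps - 1) / 2` samples is compensated,
#' so the output is time-aligned with the input and has the same length.
#'
#' @param rec An [eeg_recording()].
#' @param lo_hz,hi_hz Band edges in Hz, `0 < lo < hi < fs / 2`.
#' @param taps Filter length (odd; default 513, about one second at 512 Hz,
#'   adequate for an 8 Hz lower edge).
#' @return The filtered recording.
#' @export
fir_bandpass <- function(rec, lo_hz, hi_hz, taps = 513) {
  fs <- rec$fs
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs / 2)) {
    stop("invalid band: need 0 < lo < hi < fs/2", call. = FALSE)
  }
  if (taps %% 2L == 0L) stop("taps must be odd", call. = FALSE)
  b <- signal::fir1(taps - 1L, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  g <- (taps - 1L) %/% 2L
  out <- rec
  out$samples <- t(apply(rec$samples, 1L, .filt_reflect, b = b, g = g))
  out
}

# Convolve one channel with FIR taps b, reflection padding of g samples at
# each end, centre-aligned output of the original length.
.filt_reflect <- function(x, b, g) {
  L <- length(x)
  gl <- min(g, L - 1L)
  pad <- c(rev(x[2:(gl + 1L)]), x, rev(x[(L - gl):(L - 1L)]))
  z <- stats::convolve(pad, rev(b), type = "open")
  z[(gl + g + 1L):(gl + g + L)]
}

#' Segment a recording into trial epochs
#'
#' Cuts one fixed-length epoch per trial onset. Onsets too close to the end
#' of the recording for a full epoch are dropped with a warning.
#'
#' @param rec An [eeg_recording()] with onsets.
#' @param epoch_len_s Epoch length in seconds from each onset (default 1,
#'   the stimulus-on window).
#' @return An `epoch_set`: trials x channels x samples array plus metadata.
#' @export
segment <- function(rec, epoch_len_s = 1.0) {
  n_samp <- round(epoch_len_s * rec$fs)
  ok <- rec$onsets + n_samp - 1L <= ncol(rec$samples)
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) dropped: epoch extends past the recording")
  }
  onsets <- rec$onsets[ok]
  if (length(onsets) == 0L) stop("no complete epochs", call. = FALSE)
  nch <- nrow(rec$samples)
  dat <- array(0, dim = c(length(onsets), nch, n_samp))
  for (i in seq_along(onsets)) {
    dat[i, , ] <- rec$samples[, onsets[i]:(onsets[i] + n_samp - 1L)]
  }
  structure(list(data = dat, fs = rec$fs, channel_names = rec$channel_names,
                 kept_trial_ids = which(ok)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Amplitude-based artefact rejection
#'
#' Discards trials in which any channel exceeds the amplitude threshold in
#' absolute value (strictly larger than; default 100 microvolts, the upper
#' bound of normal scalp EEG — larger excursions are taken as body movements
#' or other artefacts).
#'
#' @param epochs An `epoch_set`.
#' @param threshold_uv Rejection threshold in microvolts.
#' @return The epoch set with offending trials removed and
#'   `kept_trial_ids` updated.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 100) {
  stopifnot(threshold_uv > 0)
  peak <- apply(abs(epochs$data), 1L, max)
  keep <- peak <= threshold_uv
  if (!any(keep)) stop("all trials rejected as artefacts", call. = FALSE)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$kept_trial_ids <- epochs$kept_trial_ids[keep]
  epochs
}

#' Power spectral density of one signal segment
#'
#' Raw-FFT periodogram: coefficients `x(k) = sum_n x(n) e^(-i 2 pi n k / N)`
#' and power `P(k) = |x(k)|^2 / N` (no taper, no zero padding), which makes
#' the Parseval identity `sum_k P(k) = sum_n x(n)^2` exact.
#'
#' @param x Numeric vector (one channel, one segment).
#' @param fs Sampling rate in Hz.
#' @return An object of class `eeg_spectrum` with fields `coeffs`, `power`,
#'   `freq`, `N`, `fs`.
#' @export
psd <- function(x, fs) {
  N <- length(x)
  if (N < 2L) stop("signal too short", call. = FALSE)
  co <- stats::fft(x)
  structure(list(coeffs = co, power = Mod(co)^2 / N,
                 freq = (0:(N - 1L)) * fs / N, N = N, fs = fs),
            class = "eeg_spectrum")
}

#' Band-limited spectral shape features
#'
#' Three scalar summaries of the in-band power distribution:
#' * `concavity` — the quadratic coefficient of a least-squares parabola
#'   fitted to `log10(P + 1e-12)` over the in-band bins (how peaked vs flat
#'   the log-spectrum is);
#' * `power_variance` — the variance of the in-band power values;
#' * `nondominant_ratio` — one minus the fraction of in-band power lying
#'   within 1 Hz of the in-band peak (how much power sits outside the
#'   dominant spectral region).
#'
#' These are explicit operationalizations of qualitative spectral-shape
#' descriptors ("concavity", "variance", "nondominant region"); no canonical
#' closed form exists for them, so the definitions above are this package's
#' documented surrogates.
#'
#' @param spec An [psd()] result.
#' @param band Length-2 numeric, band edges in Hz (within Nyquist).
#' @return A named list with the three features.
#' @export
psd_features <- function(spec, band) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (band[2] > spec$fs / 2) stop("band beyond Nyquist", call. = FALSE)
  sel <- which(spec$freq >= band[1] & spec$freq <= band[2] &
                 spec$freq <= spec$fs / 2)
  if (length(sel) < 3L) stop("fewer than 3 in-band bins", call. = FALSE)
  f <- spec$freq[sel]
  p <- spec$power[sel]
  fit <- stats::lm.fit(cbind(1, f, f^2), log10(p + 1e-12))
  peak_f <- f[which.max(p)]
  near <- abs(f - peak_f) <= 1
  tot <- sum(p)
  list(concavity = unname(fit$coefficients[3L]),
       power_variance = stats::var(p),
       nondominant_ratio = if (tot > 0) 1 - sum(p[near]) / tot else 0)
}

# Complex Morlet kernel at centre frequency fc (Hz): psi(t) proportional to
# exp(i omega0 t / s) exp(-(t/s)^2 / 2), s = omega0 / (2 pi fc), support 4s
# per side. Returns list(kernel, half_support_samples).
.morlet_kernel <- function(fc, fs, omega0 = 6) {
  s <- omega0 / (2 * pi * fc)
  hs <- ceiling(4 * s * fs)
  t <- (-hs:hs) / fs
  k <- exp(1i * omega0 * t / s) * exp(-(t / s)^2 / 2)
  list(kernel = k / sqrt(s), half_support = hs)
}

# Centre-aligned complex convolution of a real signal with a wavelet kernel
# (reflection padding).
.cwt_one <- function(x, kern) {
  hs <- kern$half_support
  L <- length(x)
  gl <- min(hs, L - 1L)
  pad <- c(rev(x[2:(gl + 1L)]), x, rev(x[(L - gl):(L - 1L)]))
  k <- kern$kernel
  zr <- stats::convolve(pad, rev(Re(k)), type = "open")
  zi <- stats::convolve(pad, rev(Im(k)), type = "open")
  z <- complex(real = zr, imaginary = zi)
  z[(gl + hs + 1L):(gl + hs + L)]
}

#' Wavelet phase stability across trials
#'
#' Inter-trial phase consistency measured with a complex Morlet wavelet at
#' the band-centre frequency: for each time point the instantaneous wavelet
#' phase is extracted per trial, and the modulus of the across-trial mean
#' unit phasor (a number in \[0, 1\], 1 = perfect phase locking) is averaged
#' over time, excluding half a wavelet support at each epoch edge where the
#' estimate is dominated by the boundary.
#'
#' @param epochs An `epoch_set` with at least 2 trials.
#' @param channel Channel name.
#' @param band Length-2 numeric band in Hz; the wavelet is centred at its
#'   midpoint.
#' @param omega0 Morlet time-frequency parameter (default 6).
#' @return A list with `gamma` (the scalar phase-stability value),
#'   `gamma_t` (the time-resolved curve), `fc`, and `M` (trial count).
#' @export
wps <- function(epochs, channel, band, omega0 = 6) {
  M <- dim(epochs$data)[1L]
  if (M < 2L) stop("need at least 2 trials", call. = FALSE)
  ch <- match(channel, epochs$channel_names)
  if (is.na(ch)) stop("unknown channel: ", channel, call. = FALSE)
  fc <- mean(band)
  kern <- .morlet_kernel(fc, epochs$fs, omega0)
  L <- dim(epochs$data)[3L]
  phasor <- matrix(0 + 0i, M, L)
  for (m in seq_len(M)) {
    z <- .cwt_one(epochs$data[m, ch, ], kern)
    phasor[m, ] <- exp(1i * Arg(z))
  }
  gamma_t <- Mod(colMeans(phasor))
  hs <- min(kern$half_support, (L - 1L) %/% 2L)
  interior <- (hs + 1L):(L - hs)
  list(gamma = mean(gamma_t[interior]), gamma_t = gamma_t, fc = fc, M = M)
}

#' Magnitude-squared coherence between two channels
#'
#' `C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))` with auto- and cross-spectra
#' estimated per trial (Hann taper to control leakage) and averaged across
#' trials before the ratio is formed. Averaging over at least two segments is
#' required: single-segment coherence is identically 1.
#'
#' @param epochs An `epoch_set` with at least 2 trials.
#' @param ch_a,ch_b Channel names.
#' @param band Length-2 numeric band in Hz for `band_mean`.
#' @return A list with `band_mean`, `cxy` (per-frequency coherence, clipped
#'   to \[0, 1\]), and `freq`.
#' @export
coherence <- function(epochs, ch_a, ch_b, band) {
  M <- dim(epochs$data)[1L]
  if (M < 2L) stop("need at least 2 trials", call. = FALSE)
  ia <- match(ch_a, epochs$channel_names)
  ib <- match(ch_b, epochs$channel_names)
  if (is.na(ia) || is.na(ib)) stop("unknown channel", call. = FALSE)
  L <- dim(epochs$data)[3L]
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / (L - 1L))
  pxx <- pyy <- numeric(L)
  pxy <- complex(length.out = L)
  for (m in seq_len(M)) {
    X <- stats::fft(epochs$data[m, ia, ] * w)
    Y <- stats::fft(epochs$data[m, ib, ] * w)
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  pxx <- pxx / M; pyy <- pyy / M; pxy <- pxy / M
  cxy <- rep(NA_real_, L)
  ok <- pxx > 0 & pyy > 0
  cxy[ok] <- pmin(pmax(Mod(pxy[ok])^2 / (pxx[ok] * pyy[ok]), 0), 1)
  freq <- (0:(L - 1L)) * epochs$fs / L
  sel <- which(freq >= band[1] & freq <= band[2] & freq <= epochs$fs / 2 & ok)
  list(band_mean = mean(cxy[sel]), cxy = cxy, freq = freq)
}

#' Build the distraction-descriptor feature table
#'
#' Assembles one feature vector per trial from band-filtered epoch sets:
#' for every channel and band the three [psd_features()] values and the
#' [wps()] phase stability, and for every listed channel pair and band the
#' [coherence()] band mean. WPS and coherence are multi-trial statistics, so
#' they are computed over a sliding block of the `block` most recent trials
#' and assigned to the block's last trial (the first trial uses the block
#' ending at the second trial, the smallest window for which the statistics
#' exist).
#'
#' With the default 5-channel montage, two bands and two occipital pairs the
#' table has 5 x 2 x 3 + 5 x 2 + 2 x 2 = 44 named features per trial.
#'
#' @param epochs_by_band Named list of `epoch_set`s, one per band (same
#'   trials in each).
#' @param bands Named list of length-2 numeric band edges in Hz matching
#'   `epochs_by_band` (default alpha 8-13, beta 13-30).
#' @param channels Channel names to use (default: all in the epoch sets).
#' @param pairs List of channel-name pairs for coherence (default O1-OZ and
#'   OZ-O2).
#' @param block Sliding-block length for WPS and coherence (default 10).
#' @param labels Optional per-trial class labels added as a `class` column.
#' @return A tibble, one row per trial: `trial` id, features, and optionally
#'   `class`.
#' @export
build_descriptor <- function(epochs_by_band,
                             bands = list(alpha = c(8, 13), beta = c(13, 30)),
                             channels = NULL,
                             pairs = list(c("O1", "OZ"), c("OZ", "O2")),
                             block = 10, labels = NULL) {
  stopifnot(length(epochs_by_band) >= 1L,
            all(names(epochs_by_band) %in% names(bands)))
  first <- epochs_by_band[[1L]]
  if (is.null(channels)) channels <- first$channel_names
  bad <- setdiff(unique(c(channels, unlist(pairs))), first$channel_names)
  if (length(bad) > 0L) stop("unknown channel: ", paste(bad, collapse = ", "),
                             call. = FALSE)
  n_trials <- dim(first$data)[1L]
  out <- list(trial = first$kept_trial_ids)

  for (bn in names(epochs_by_band)) {
    ep <- epochs_by_band[[bn]]
    band <- bands[[bn]]
    fs <- ep$fs
    L <- dim(ep$data)[3L]
    # per-trial PSD shape features
    for (ch in channels) {
      ci <- match(ch, ep$channel_names)
      conc <- pv <- nd <- numeric(n_trials)
      for (i in seq_len(n_trials)) {
        fe <- psd_features(psd(ep$data[i, ci, ], fs), band)
        conc[i] <- fe$concavity; pv[i] <- fe$power_variance
        nd[i] <- fe$nondominant_ratio
      }
      out[[paste0("psd_", ch, "_", bn, "_concavity")]] <- conc
      out[[paste0("psd_", ch, "_", bn, "_powervar")]] <- pv
      out[[paste0("psd_", ch, "_", bn, "_nondom")]] <- nd
    }
    # sliding-block WPS: one wavelet pass per trial, rolling phasor means
    kern <- .morlet_kernel(mean(band), fs)
    hs <- min(kern$half_support, (L - 1L) %/% 2L)
    interior <- (hs + 1L):(L - hs)
    for (ch in channels) {
      ci <- match(ch, ep$channel_names)
      phasor <- matrix(0 + 0i, n_trials, L)
      for (m in seq_len(n_trials)) {
        phasor[m, ] <- exp(1i * Arg(.cwt_one(ep$data[m, ci, ], kern)))
      }
      g <- numeric(n_trials)
      for (i in seq_len(n_trials)) {
        rows <- .block_rows(i, block, n_trials)
        g[i] <- mean(Mod(colMeans(phasor[rows, , drop = FALSE]))[interior])
      }
      out[[paste0("wps_", ch, "_", bn)]] <- g
    }
    # sliding-block coherence: one tapered FFT per trial/channel, rolling
    # cross-spectral averages
    if (length(pairs) > 0L) {
      w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / (L - 1L))
      freq <- (0:(L - 1L)) * fs / L
      sel <- which(freq >= band[1] & freq <= band[2] & freq <= fs / 2)
      pair_ch <- unique(unlist(pairs))
      ffts <- lapply(pair_ch, function(ch) {
        ci <- match(ch, ep$channel_names)
        t(vapply(seq_len(n_trials),
                 function(m) stats::fft(ep$data[m, ci, ] * w),
                 complex(L)))
      })
      names(ffts) <- pair_ch
      for (pr in pairs) {
        FX <- ffts[[pr[1L]]]; FY <- ffts[[pr[2L]]]
        cm <- numeric(n_trials)
        for (i in seq_len(n_trials)) {
          rows <- .block_rows(i, block, n_trials)
          X <- FX[rows, sel, drop = FALSE]; Y <- FY[rows, sel, drop = FALSE]
          pxx <- colMeans(Mod(X)^2); pyy <- colMeans(Mod(Y)^2)
          pxy <- colMeans(X * Conj(Y))
          ok <- pxx > 0 & pyy > 0
          cm[i] <- mean(pmin(Mod(pxy[ok])^2 / (pxx[ok] * pyy[ok]), 1))
        }
        out[[paste0("coh_", pr[1L], "_", pr[2L], "_", bn)]] <- cm
      }
    }
  }
  tb <- tibble::as_tibble(out)
  if (!is.null(labels)) tb$class <- as.character(labels)[first$kept_trial_ids]
  tb
}

# Rows of the sliding block ending at trial i (length <= block, always >= 2
# when n >= 2: the first trial borrows the block ending at trial 2).
.block_rows <- function(i, block, n) {
  if (i == 1L && n >= 2L) i <- 2L
  max(1L, i - block + 1L):i
}
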