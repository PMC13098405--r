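#' Frame configuration for short-time analysis
#'
#' @param window_s Analysis window length in seconds (default 25 ms).
#' @param hop_s Hop between frames in seconds (default 10 ms).
#' @param n_mel Number of mel filters for the MFCC filterbank.
#' @param n_mfcc Number of MFCC coefficients kept (default 13).
#' @param n_contrast_bands Number of spectral-contrast octave bands.
#' @param rolloff Spectral rolloff energy fraction (default 0.85).
#' @param flux_smooth Frames of moving-average smoothing applied to the
#'   octave-band spectrogram before flux differencing; suppresses the
#'   stochastic frame-to-frame variation of stationary signals so flux tracks
#'   genuine spectral change.
#' @return Object of class `frame_config`.
#' @export
frame_config <- function(window_s = 0.025, hop_s = 0.010, n_mel = 26,
                         n_mfcc = 13, n_contrast_bands = 6, rolloff = 0.85,
                         flux_smooth = 15) {
  structure(list(window_s = window_s, hop_s = hop_s, n_mel = n_mel,
                 n_mfcc = n_mfcc, n_contrast_bands = n_contrast_bands,
                 rolloff = rolloff, flux_smooth = flux_smooth),
            class = "frame_config")
}

## Split a signal into a (n_frame x frame_len) matrix of windowed frames.
frame_signal <- function(x, frame_len, hop) {
  n <- length(x)
  if (frame_len > n) stopf("frame (%d samples) longer than signal (%d)", frame_len, n)
  starts <- seq(1L, n - frame_len + 1L, by = hop)
  matrix(x[outer(starts, 0:(frame_len - 1L), "+")], nrow = length(starts))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

## Magnitude spectrogram: rows = frames, cols = frequency bins (0..Nyquist).
stft_mag <- function(x, sr, cfg) {
  frame_len <- round(cfg$window_s * sr)
  hop <- max(1L, round(cfg$hop_s * sr))
  frames <- frame_signal(x, frame_len, hop)
  win <- hann_window(frame_len)
  wf <- sweep(frames, 2, win, "*")
  spec <- Mod(t(stats::mvfft(t(wf))))
  n_bins <- floor(frame_len / 2) + 1L
  list(mag = spec[, seq_len(n_bins), drop = FALSE],
       freqs = (seq_len(n_bins) - 1) * sr / frame_len,
       frames = frames, hop = hop, frame_len = frame_len)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(freqs, sr, n_mel) {
  pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(sr / 2), length.out = n_mel + 2))
  fb <- matrix(0, n_mel, length(freqs))
  for (m in seq_len(n_mel)) {
    lo <- pts[m]; mid <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

moving_avg_rows <- function(m, k) {
  if (k <= 1 || nrow(m) < 2) return(m)
  kern <- rep(1 / k, k)
  apply(m, 2, function(col) as.numeric(stats::filter(col, kern, sides = 2)))
}

#' Spectral and cepstral features of a recording
#'
#' Computes framewise descriptors and reduces them to per-recording means and
#' SDs: spectral centroid, rolloff, flux, per-band spectral contrast, per-bin
#' chroma, MFCCs and delta-MFCCs, and frame RMS energy. Flux is the L2 norm of
#' the difference of consecutive time-smoothed mel-band spectra (see
#' [frame_config()]); silent frames yield zero centroid/rolloff.
#'
#' @param audio An [audio_wave()] (collapsed to mono).
#' @param cfg A [frame_config()].
#' @return Named numeric vector (a sub-map of the feature catalog).
#' @export
spectral_features <- function(audio, cfg = frame_config()) {
  audio <- audio_mono(audio)
  x <- audio$samples
  sr <- audio$sample_rate
  st <- stft_mag(x, sr, cfg)
  mag <- st$mag; freqs <- st$freqs
  tot <- rowSums(mag)
  nz <- tot > 0
  centroid <- ifelse(nz, as.numeric(mag %*% freqs) / pmax(tot, 1e-300), 0)
  ## rolloff: lowest frequency below which `rolloff` of the energy lies
  energy <- mag^2
  cume <- t(apply(energy, 1, cumsum))
  etot <- cume[, ncol(cume)]
  roll_idx <- apply(cume >= cfg$rolloff * pmax(etot, 1e-300), 1, which.max)
  rolloff <- ifelse(etot > 0, freqs[roll_idx], 0)
  ## RMS energy per frame (time domain)
  rmse <- sqrt(rowMeans(st$frames^2))
  ## mel spectrogram for flux + MFCC
  fb <- mel_filterbank(freqs, sr, cfg$n_mel)
  melspec <- energy %*% t(fb)                      # frames x mel
  ## flux on a coarse (octave-band), time-smoothed LOG-magnitude
  ## spectrogram: wide bands average out stochastic bin-to-bin variation,
  ## the moving average suppresses residual frame-to-frame noise, and the
  ## log scale (with a relative floor) makes genuine level/spectral change
  ## dominate the stationary fluctuation floor
  oct_edges <- c(0, 200 * 2^(0:4), sr / 2)
  band_mag <- vapply(seq_len(length(oct_edges) - 1), function(b) {
    cols <- which(freqs >= oct_edges[b] & freqs < oct_edges[b + 1])
    if (length(cols)) sqrt(rowMeans(energy[, cols, drop = FALSE])) else
      numeric(nrow(energy))
  }, numeric(nrow(mag)))
  if (is.null(dim(band_mag))) band_mag <- matrix(band_mag, nrow = 1)
  peak_bm <- max(band_mag)
  log_bm <- if (peak_bm > 0) log(band_mag + 1e-4 * peak_bm) - log(1e-4 * peak_bm)
            else band_mag
  sm <- moving_avg_rows(log_bm, cfg$flux_smooth)
  keep <- stats::complete.cases(sm)
  flux <- if (sum(keep) > 1) {
    d <- diff(sm[keep, , drop = FALSE])
    sqrt(rowSums(d^2))
  } else 0
  ## MFCC: log mel energies -> orthonormal DCT-II
  logmel <- log(melspec + 1e-10)
  n_in <- cfg$n_mel
  k <- 0:(cfg$n_mfcc - 1)
  dct_mat <- outer(k, seq_len(n_in) - 0.5, function(kk, nn) cos(pi * kk * nn / n_in)) *
    sqrt(2 / n_in)
  dct_mat[1, ] <- dct_mat[1, ] / sqrt(2)
  mfcc <- logmel %*% t(dct_mat)                    # frames x n_mfcc
  dmfcc <- if (nrow(mfcc) >= 3) {
    (mfcc[c(3:nrow(mfcc), nrow(mfcc)), ] - mfcc[c(1, 1:(nrow(mfcc) - 2)), ]) / 2
  } else mfcc * 0
  ## spectral contrast: octave bands, peak minus valley of log magnitudes
  edges <- 200 * 2^(0:(cfg$n_contrast_bands))
  edges[length(edges)] <- max(edges[length(edges)], sr / 2)
  contrast <- matrix(NA_real_, nrow(mag), cfg$n_contrast_bands)
  alpha <- 0.2
  for (b in seq_len(cfg$n_contrast_bands)) {
    lo <- if (b == 1) 0 else edges[b]
    hi <- edges[b + 1]
    cols <- which(freqs >= lo & freqs < hi)
    if (!length(cols)) next
    sub <- mag[, cols, drop = FALSE]
    q <- max(1L, round(alpha * length(cols)))
    srt <- t(apply(sub, 1, sort))
    valley <- log(rowMeans(srt[, seq_len(q), drop = FALSE]) + 1e-10)
    peak <- log(rowMeans(srt[, (ncol(srt) - q + 1):ncol(srt), drop = FALSE]) + 1e-10)
    contrast[, b] <- peak - valley
  }
  ## chroma: fold bin energy onto 12 pitch classes, frame-normalized to max 1
  audible <- freqs >= 30
  pc <- (round(12 * log2(pmax(freqs, 1) / 440) + 69) %% 12)
  chroma_raw <- vapply(0:11, function(p) {
    cols <- which(audible & pc == p)
    if (length(cols)) rowSums(energy[, cols, drop = FALSE]) else numeric(nrow(energy))
  }, numeric(nrow(energy)))
  if (is.null(dim(chroma_raw))) chroma_raw <- matrix(chroma_raw, nrow = 1)
  peak_c <- apply(chroma_raw, 1, max)
  chroma <- sweep(chroma_raw, 1, pmax(peak_c, 1e-300), "/")
  chroma[peak_c == 0, ] <- 0

  out <- c(
    spectral_centroid_mean = mean(centroid), spectral_centroid_sd = pop_sd(centroid),
    spectral_rolloff_mean = mean(rolloff), spectral_rolloff_sd = pop_sd(rolloff),
    spectral_flux_mean = mean(flux), spectral_flux_sd = pop_sd(flux),
    rmse_mean = mean(rmse), rmse_sd = pop_sd(rmse),
    setNames(colMeans(contrast, na.rm = TRUE),
             sprintf("spectral_contrast_mean_%d", 0:(cfg$n_contrast_bands - 1))),
    setNames(apply(contrast, 2, pop_sd),
             sprintf("spectral_contrast_sd_%d", 0:(cfg$n_contrast_bands - 1))),
    setNames(colMeans(chroma), sprintf("chroma_mean_%d", 0:11)),
    setNames(colMeans(mfcc), sprintf("mfcc_mean_%d", 1:cfg$n_mfcc)),
    setNames(apply(mfcc, 2, pop_sd), sprintf("mfcc_sd_%d", 1:cfg$n_mfcc)),
    setNames(colMeans(dmfcc), sprintf("dmfcc_mean_%d", 1:cfg$n_mfcc)),
    setNames(apply(dmfcc, 2, pop_sd), sprintf("dmfcc_sd_%d", 1:cfg$n_mfcc))
  )
  out
}
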