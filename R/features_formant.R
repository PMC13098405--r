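## Autocorrelation-method LPC with a Gaussian lag window. The lag window
## smooths the short-term spectrum (kernel ~ sigma_hz), collapsing the
## harmonic line structure of voiced frames into the spectral envelope so
## the prediction polynomial models the resonances, not individual
## harmonics; estimated bandwidths are inflated by roughly the kernel width
## but stay monotone in the true resonance damping.
lpc_lagwindow <- function(fr, order, sigma_hz, sr) {
  n <- length(fr)
  fr <- fr - mean(fr)
  nfft <- 2^ceiling(log2(2 * n))
  sp <- fft(c(fr, numeric(nfft - n)))
  ac <- Re(fft(Mod(sp)^2, inverse = TRUE))[1:(order + 1)] / nfft
  if (ac[1] <= 0) return(NULL)
  lag_sd <- sr / (2 * pi * sigma_hz)
  ac <- ac * exp(-0.5 * ((0:order) / lag_sd)^2)
  ## Levinson-Durbin via a Toeplitz solve
  r0 <- ac[1] * (1 + 1e-9)
  R <- stats::toeplitz(c(r0, ac[2:order]))
  a <- tryCatch(solve(R, ac[2:(order + 1)]), error = function(e) NULL)
  a
}

#' Formant features via linear-prediction root-finding
#'
#' Tracks the first three formants over voiced frames: each 25 ms frame is
#' pre-emphasized, Hann-windowed, fit with a Burg linear-prediction model,
#' and the complex roots of the prediction polynomial are converted to
#' resonance frequencies (`angle/(2*pi) * sr`) and bandwidths
#' (`-sr/pi * log(|root|)`). Poles with bandwidth under 1.2 kHz and frequency
#' in (150 Hz, 0.95 * Nyquist) are formant candidates; the three lowest are
#' F1-F3. Summaries: F1/F2/F3 track means, F2/F3 coefficient of variation,
#' and mean bandwidths B2/B3. Unvoiced-only audio yields all-missing values.
#'
#' @param audio An [audio_wave()].
#' @param lpc_order Linear-prediction order (default 18 at 16 kHz).
#' @param f0_range Pitch range used to locate voiced frames.
#' @return Named numeric vector: `f1_mean`, `f2_mean`, `f3_mean`, `f2_cv`,
#'   `f3_cv`, `b2_mean`, `b3_mean`.
#' @export
formant_features <- function(audio, lpc_order = NULL, f0_range = c(60, 400)) {
  audio <- audio_mono(audio)
  x <- audio$samples; sr <- audio$sample_rate
  lpc_order <- lpc_order %||% max(10L, round(2 + sr / 1000) + 2)
  pitch <- track_pitch(x, sr, f0_range)
  voiced_times <- pitch$time[!is.na(pitch$f0)]
  nil <- c(f1_mean = NA_real_, f2_mean = NA_real_, f3_mean = NA_real_,
           f2_cv = NA_real_, f3_cv = NA_real_,
           b2_mean = NA_real_, b3_mean = NA_real_)
  if (!length(voiced_times)) return(nil)
  frame_len <- round(0.025 * sr)
  win <- hann_window(frame_len)
  pre <- c(x[1], x[-1] - 0.97 * x[-length(x)])
  tracks <- matrix(NA_real_, length(voiced_times), 3)
  bands <- matrix(NA_real_, length(voiced_times), 3)
  for (i in seq_along(voiced_times)) {
    start <- round(voiced_times[i] * sr - frame_len / 2)
    if (start < 1 || start + frame_len - 1 > length(pre)) next
    fr <- pre[start:(start + frame_len - 1)] * win
    a <- lpc_lagwindow(fr, lpc_order, sigma_hz = 70, sr = sr)
    if (is.null(a) || !length(a)) next
    ## polyroot works on ascending powers of z, i.e. it returns the
    ## reciprocals of the prediction-polynomial poles
    poles <- 1 / polyroot(c(1, -a))
    freq <- Arg(poles) / (2 * pi) * sr
    bw <- -sr / pi * log(pmin(Mod(poles), 1 - 1e-12))
    keep <- freq > 150 & freq < 0.95 * sr / 2 & bw < 1200
    cand <- sort(freq[keep])
    if (length(cand) >= 1) {
      sel <- order(freq[keep])
      f_sorted <- freq[keep][sel]; b_sorted <- bw[keep][sel]
      k <- min(3, length(f_sorted))
      tracks[i, seq_len(k)] <- f_sorted[seq_len(k)]
      bands[i, seq_len(k)] <- b_sorted[seq_len(k)]
    }
  }
  cv <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    pop_sd(v) / mean(v)
  }
  mn <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  c(f1_mean = mn(tracks[, 1]), f2_mean = mn(tracks[, 2]), f3_mean = mn(tracks[, 3]),
    f2_cv = cv(tracks[, 2]), f3_cv = cv(tracks[, 3]),
    b2_mean = mn(bands[, 2]), b3_mean = mn(bands[, 3]))
}
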