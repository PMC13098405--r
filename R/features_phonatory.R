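## ---- pitch tracking -------------------------------------------------------

## Autocorrelation pitch + voicing decision per frame. Returns a data frame
## with one row per frame: f0 (NA if unvoiced), harmonicity r in [0,1).
track_pitch <- function(x, sr, f0_range = c(60, 400), frame_s = 0.04,
                        hop_s = 0.01, voicing_threshold = 0.45) {
  frame_len <- round(frame_s * sr)
  hop <- max(1L, round(hop_s * sr))
  if (frame_len > length(x)) stopf("frame longer than signal")
  frames <- frame_signal(x, frame_len, hop)
  lag_min <- max(2L, floor(sr / f0_range[2]))
  lag_max <- min(frame_len - 2L, ceiling(sr / f0_range[1]))
  if (lag_min >= lag_max) stopf("f0_range incompatible with frame length")
  rms_all <- sqrt(rowMeans(frames^2))
  peak_rms <- max(rms_all, 1e-12)
  n_frames <- nrow(frames)
  f0 <- rep(NA_real_, n_frames); harm <- rep(NA_real_, n_frames)
  for (i in seq_len(n_frames)) {
    fr <- frames[i, ] - mean(frames[i, ])
    if (rms_all[i] < 0.03 * peak_rms) next   # silence gate
    ## autocorrelation via FFT
    nfft <- 2^ceiling(log2(2 * frame_len))
    sp <- fft(c(fr, numeric(nfft - frame_len)))
    ac <- Re(fft(Mod(sp)^2, inverse = TRUE))[1:(lag_max + 2L)]
    if (ac[1] <= 0) next
    ## unbiased normalization: the linear autocorrelation at lag L only
    ## overlaps N - L samples, so rescale by N / (N - L)
    lags <- 0:(lag_max + 1L)
    ac <- ac / ac[1] * frame_len / pmax(frame_len - lags, 1)
    seg <- ac[(lag_min + 1L):(lag_max + 1L)]
    m <- max(seg)
    ## octave preference: a perfectly periodic signal peaks equally at every
    ## multiple of the period; take the SHORTEST lag whose local maximum is
    ## within tolerance of the global one to avoid subharmonic errors
    is_locmax <- c(FALSE, diff(seg) > 0) & c(diff(seg) < 0, FALSE)
    cand <- which(is_locmax & seg >= m - 0.02)
    j <- if (length(cand)) cand[1] else which.max(seg)
    r <- seg[j]
    lag <- lag_min + j - 1L
    ## parabolic interpolation around the peak for fractional lag and height
    if (lag > lag_min && lag < lag_max) {
      y1 <- ac[lag]; y2 <- ac[lag + 1L]; y3 <- ac[lag + 2L]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > 1e-12) {
        delta <- 0.5 * (y1 - y3) / denom
        delta <- max(-0.5, min(0.5, delta))
        lag_f <- lag + delta
        ## parabolic height refinement; clamp implausible overshoot
        r <- min(y2 - 0.25 * (y1 - y3) * delta, y2 + abs(y3 - y1))
      } else lag_f <- lag
    } else lag_f <- lag
    if (r >= voicing_threshold) {
      f0[i] <- sr / lag_f
      harm[i] <- max(min(r, 1 - 1e-12), 0)
    }
  }
  data.frame(frame = seq_len(n_frames), f0 = f0, harmonicity = harm,
             time = (seq_len(n_frames) - 1) * hop / sr + frame_s / 2)
}

## ---- cycle-level period/amplitude estimation ------------------------------

## Band-pass the signal around f0 via FFT masking, then pick one positive
## peak per cycle with parabolic interpolation -> cycle times + amplitudes.
estimate_cycles <- function(x, sr, f0_med) {
  n <- length(x)
  sp <- fft(x)
  freqs <- (0:(n - 1)) * sr / n
  freqs_fold <- pmin(freqs, sr - freqs)
  ## generous band around f0: cycle-rate jitter modulates the fundamental
  ## with sidebands out to ~0.5 f0 either side; a narrower mask truncates
  ## them and shrinks the measured perturbation
  mask <- freqs_fold >= 0.25 * f0_med & freqs_fold <= 1.75 * f0_med
  xf <- Re(fft(sp * mask, inverse = TRUE)) / n
  t0 <- sr / f0_med                       # expected period (samples)
  ## first peak: maximum in the first two expected periods
  lim <- min(n, ceiling(2 * t0))
  peaks_t <- numeric(0); peaks_a <- numeric(0)
  i <- which.max(xf[1:lim])
  repeat {
    ## refine peak by parabolic interpolation
    if (i > 1 && i < n) {
      y1 <- xf[i - 1]; y2 <- xf[i]; y3 <- xf[i + 1]
      denom <- y1 - 2 * y2 + y3
      delta <- if (abs(denom) > 1e-15) max(-0.5, min(0.5, 0.5 * (y1 - y3) / denom)) else 0
      t_pk <- i + delta
      a_pk <- y2 - 0.25 * (y1 - y3) * delta
    } else { t_pk <- i; a_pk <- xf[i] }
    peaks_t <- c(peaks_t, t_pk); peaks_a <- c(peaks_a, a_pk)
    lo <- round(i + 0.7 * t0); hi <- round(i + 1.3 * t0)
    if (hi > n) break
    i <- lo + which.max(xf[lo:hi]) - 1L
  }
  ## periods by waveform matching: each cycle window is cross-correlated
  ## with the signal one period ahead, and the best-aligning lag is the
  ## cycle's period (parabolic refinement for sub-sample lags). This tracks
  ## the true glottal timing where narrowband peak/phase estimates smear
  ## the cycle-to-cycle perturbation.
  w <- max(8L, round(t0))
  lags <- floor(0.7 * t0):ceiling(1.3 * t0)
  periods <- rep(NA_real_, max(length(peaks_t) - 1L, 0L))
  for (ci in seq_len(length(peaks_t) - 1L)) {
    a0 <- round(peaks_t[ci] - 0.5 * t0)
    if (a0 < 1 || a0 + w + max(lags) + 1L > n) next
    seg <- x[a0:(a0 + w)]
    e_seg <- sum(seg^2)
    if (e_seg <= 0) next
    cc <- vapply(lags, function(L) {
      s2 <- x[(a0 + L):(a0 + L + w)]
      den <- sqrt(e_seg * sum(s2^2))
      if (den > 0) sum(seg * s2) / den else 0
    }, 0)
    j <- which.max(cc)
    lag_best <- lags[j]
    if (j > 1 && j < length(cc)) {
      den <- cc[j - 1] - 2 * cc[j] + cc[j + 1]
      if (abs(den) > 1e-15) {
        lag_best <- lag_best +
          max(-0.5, min(0.5, 0.5 * (cc[j - 1] - cc[j + 1]) / den))
      }
    }
    periods[ci] <- lag_best / sr
  }
  list(times = peaks_t / sr, amps = peaks_a, periods = periods)
}

## ---- perturbation measures on period / amplitude sequences ----------------

#' Jitter measures from a cycle period sequence
#'
#' `jitter_local` is the mean absolute difference between consecutive periods
#' divided by the mean period; `jitter_rap` (relative average perturbation)
#' compares each interior period to the 3-point local mean.
#'
#' @param periods Numeric vector of cycle periods (seconds).
#' @return Named vector `jitter_local`, `jitter_rap` (NA if < 3 periods).
#' @export
jitter_measures <- function(periods) {
  p <- periods[!is.na(periods)]
  if (length(p) < 3) return(c(jitter_local = NA_real_, jitter_rap = NA_real_))
  mp <- mean(p)
  local <- mean(abs(diff(p))) / mp
  n <- length(p)
  rap <- mean(abs(p[2:(n - 1)] - (p[1:(n - 2)] + p[2:(n - 1)] + p[3:n]) / 3)) / mp
  c(jitter_local = local, jitter_rap = rap)
}

#' Shimmer measures from a cycle amplitude sequence
#'
#' `shimmer_local` is the mean absolute difference of consecutive cycle
#' amplitudes over the mean amplitude; `shimmer_apq5` compares each cycle to
#' its 5-point local mean; `shimmer_dda` averages the absolute second
#' differences of the amplitude sequence over the mean amplitude.
#'
#' @param amps Numeric vector of per-cycle amplitudes.
#' @return Named vector `shimmer_local`, `shimmer_apq5`, `shimmer_dda`.
#' @export
shimmer_measures <- function(amps) {
  a <- amps[!is.na(amps)]
  if (length(a) < 5) {
    return(c(shimmer_local = NA_real_, shimmer_apq5 = NA_real_,
             shimmer_dda = NA_real_))
  }
  ma <- mean(a)
  n <- length(a)
  local <- mean(abs(diff(a))) / ma
  idx <- 3:(n - 2)
  five <- vapply(idx, function(i) mean(a[(i - 2):(i + 2)]), 0)
  apq5 <- mean(abs(a[idx] - five)) / ma
  dda <- mean(abs(diff(diff(a)))) / ma
  c(shimmer_local = local, shimmer_apq5 = apq5, shimmer_dda = dda)
}

## ---- main phonatory extractor ---------------------------------------------

#' Phonatory (voice quality) features
#'
#' Estimates the fundamental-frequency contour from voiced frames
#' (autocorrelation method), cycle-level period and amplitude sequences (one
#' glottal cycle per pitch period), and summarizes: F0 mean/SD/max, local and
#' RAP jitter, local/APQ5/DDA shimmer, and the harmonics-to-noise ratio in dB
#' (from the per-frame normalized autocorrelation peak,
#' `HNR = 10 log10(r / (1 - r))`, capped at 40 dB) as mean and SD over voiced
#' frames. If no voiced frames exist, every feature is returned as missing
#' (`NA`), never zero.
#'
#' @param audio An [audio_wave()].
#' @param f0_range Pitch search range in Hz (default 60-400).
#' @param voicing_threshold Minimum normalized autocorrelation for voicing.
#' @return Named numeric vector; attribute `voiced_duration_s` carries the
#'   total voiced time (used by MPT trial selection).
#' @export
phonatory_features <- function(audio, f0_range = c(60, 400),
                               voicing_threshold = 0.45) {
  audio <- audio_mono(audio)
  x <- audio$samples; sr <- audio$sample_rate
  pitch <- track_pitch(x, sr, f0_range, voicing_threshold = voicing_threshold)
  voiced <- !is.na(pitch$f0)
  nil <- c(f0_mean = NA_real_, f0_sd = NA_real_, f0_max = NA_real_,
           jitter_local = NA_real_, jitter_rap = NA_real_,
           shimmer_local = NA_real_, shimmer_apq5 = NA_real_,
           shimmer_dda = NA_real_, hnr_mean = NA_real_, hnr_sd = NA_real_)
  if (!any(voiced)) {
    attr(nil, "voiced_duration_s") <- 0
    return(nil)
  }
  f0s <- pitch$f0[voiced]
  r <- pmin(pitch$harmonicity[voiced], 1 - 1e-12)
  hnr <- pmin(10 * log10(r / (1 - r)), 40)
  cyc <- estimate_cycles(x, sr, median(f0s))
  periods <- cyc$periods
  ## keep only plausible periods (within the search range)
  ok <- !is.na(periods) & periods > 1 / f0_range[2] / 1.5 &
    periods < 1 / f0_range[1] * 1.5
  out <- c(
    f0_mean = mean(f0s), f0_sd = pop_sd(f0s), f0_max = max(f0s),
    jitter_measures(periods[ok]),
    shimmer_measures(cyc$amps),
    hnr_mean = mean(hnr), hnr_sd = pop_sd(hnr)
  )
  attr(out, "voiced_duration_s") <- sum(voiced) * 0.01
  out
}
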