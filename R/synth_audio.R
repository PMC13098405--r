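#' Parameters for synthetic sustained phonation
#'
#' Describes a sustained /a/-like vowel: a glottal pulse train at `f0_hz`
#' with controllable cycle-to-cycle period perturbation (jitter) and
#' amplitude perturbation (shimmer), vocal-tract resonances, and additive
#' noise calibrated to a target harmonics-to-noise ratio.
#'
#' @param f0_hz Fundamental frequency (> 0); default 120 Hz.
#' @param jitter_level Expected relative cycle-to-cycle period perturbation
#'   (the quantity local jitter estimates); >= 0.
#' @param shimmer_level Expected relative cycle-to-cycle amplitude
#'   perturbation (the quantity local shimmer estimates); >= 0.
#' @param hnr_db Target harmonics-to-noise ratio in dB.
#' @param formants_hz Resonance frequencies (F1, F2, F3) in Hz.
#' @param formant_bw_hz Resonance bandwidths in Hz.
#' @param duration_s Signal length in seconds (> 0).
#' @param sample_rate_hz Sampling rate; must be at least four times the
#'   highest formant (rejected otherwise).
#' @return Object of class `phonation_params`.
#' @export
phonation_params <- function(f0_hz = 120, jitter_level = 0.01,
                             shimmer_level = 0.03, hnr_db = 20,
                             formants_hz = c(700, 1200, 2600),
                             formant_bw_hz = c(80, 110, 140),
                             duration_s = 3, sample_rate_hz = 16000) {
  if (f0_hz <= 0) stopf("f0_hz must be > 0")
  if (jitter_level < 0 || shimmer_level < 0) stopf("jitter/shimmer levels must be >= 0")
  if (duration_s <= 0) stopf("duration_s must be > 0")
  if (sample_rate_hz < 4 * max(formants_hz)) {
    stopf("sample_rate_hz (%g) must be >= 4 x max formant (%g Hz)",
          sample_rate_hz, max(formants_hz))
  }
  stopifnot(length(formants_hz) == length(formant_bw_hz))
  structure(list(f0_hz = f0_hz, jitter_level = jitter_level,
                 shimmer_level = shimmer_level, hnr_db = hnr_db,
                 formants_hz = formants_hz, formant_bw_hz = formant_bw_hz,
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz),
            class = "phonation_params")
}

## Rosenberg-style glottal flow pulse sampled over one open phase.
rosenberg_pulse <- function(n_open, frac_rise = 0.6) {
  n_rise <- max(2L, round(n_open * frac_rise))
  n_fall <- max(1L, n_open - n_rise)
  t1 <- seq_len(n_rise) / n_rise
  t2 <- seq_len(n_fall) / n_fall
  c(3 * t1^2 - 2 * t1^3, 1 - t2^2)
}

## Second-order resonator applied via a recursive filter.
apply_resonator <- function(x, f_hz, bw_hz, sr) {
  r <- exp(-pi * bw_hz / sr)
  theta <- 2 * pi * f_hz / sr
  gain <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r^2)
  as.numeric(filter(gain * x, c(2 * r * cos(theta), -r^2), method = "recursive"))
}

#' Synthesize sustained phonation with controlled jitter/shimmer/HNR
#'
#' Builds a glottal pulse train whose cycle periods and amplitudes are
#' perturbed so that the *expected* local jitter and shimmer equal the
#' requested levels (Gaussian perturbations scaled by `sqrt(pi)/2` so the
#' mean absolute successive difference matches), filters it through
#' second-order resonators at the formant frequencies, differentiates
#' (radiation), and adds white noise scaled so the harmonic-to-noise power
#' ratio equals `hnr_db`. The result is peak-normalized to |x| <= 1.
#'
#' @param params A [phonation_params()].
#' @param seed Integer seed.
#' @return An [audio_wave()].
#' @export
generate_phonation_audio <- function(params, seed = 1L) {
  stopifnot(inherits(params, "phonation_params"))
  set.seed(seed)
  sr <- params$sample_rate_hz
  n <- round(params$duration_s * sr)
  t0 <- 1 / params$f0_hz
  n_cycles <- ceiling(params$duration_s * params$f0_hz) + 4L
  ## scale so E|p[i+1]-p[i]| / mean(p) = jitter_level for iid normal deviates
  scale <- sqrt(pi) / 2
  periods <- t0 * (1 + params$jitter_level * scale * rnorm(n_cycles))
  periods <- pmax(periods, 0.2 * t0)
  amps <- 1 + params$shimmer_level * scale * rnorm(n_cycles)
  amps <- pmax(amps, 0.05)
  onsets <- cumsum(c(0, periods[-n_cycles]))
  src <- numeric(n + round(sr * t0) + 9L)
  for (i in seq_len(n_cycles)) {
    ## fractional-sample pulse placement (linear interpolation) so cycle
    ## onsets are not quantized to the sample grid
    start_f <- onsets[i] * sr + 1
    i0 <- floor(start_f)
    frac <- start_f - i0
    if (i0 > n) break
    ## constant open-phase length (0.6 of the NOMINAL period): scaling the
    ## pulse with the jittered period would move each cycle's acoustic
    ## center by a fraction of the perturbation and smooth the timing
    n_open <- max(3L, round(0.6 * t0 * sr))
    pulse <- amps[i] * rosenberg_pulse(n_open)
    idx <- i0:min(i0 + length(pulse) - 1L, length(src) - 1L)
    k <- seq_along(idx)
    src[idx] <- src[idx] + (1 - frac) * pulse[k]
    src[idx + 1L] <- src[idx + 1L] + frac * pulse[k]
  }
  src <- src[seq_len(n)]
  ## radiation: differentiate the glottal flow
  harm <- diff(c(0, src))
  for (k in seq_along(params$formants_hz)) {
    harm <- apply_resonator(harm, params$formants_hz[k], params$formant_bw_hz[k], sr)
  }
  p_harm <- mean(harm^2)
  noise_sd <- sqrt(p_harm / 10^(params$hnr_db / 10))
  x <- harm + rnorm(n, 0, noise_sd)
  x <- x / max(abs(x)) * 0.98
  audio_wave(x, sr)
}
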