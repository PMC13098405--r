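check_tier <- function(tier, name) {
  if (!nrow(tier)) return(invisible(TRUE))
  if (any(tier$tmax < tier$tmin)) {
    bad <- which(tier$tmax < tier$tmin)[1]
    stopf("tier '%s': negative duration at interval %d", name, bad)
  }
  if (nrow(tier) > 1) {
    ov <- which(tier$tmin[-1] < tier$tmax[-nrow(tier)] - 1e-9)
    if (length(ov)) stopf("tier '%s': overlapping intervals at index %d", name, ov[1] + 1)
  }
  invisible(TRUE)
}

q7 <- function(x, p) unname(quantile(x, p, type = 7))

#' Temporal (alignment-derived) features
#'
#' Computes pause structure and articulation timing from word/phone interval
#' tiers. A pause is any silent gap of at least `pause_threshold_s`;
#' inter-word pauses are gaps between consecutive word intervals, intra-word
#' pauses are gaps between consecutive phone intervals inside one word.
#' Total speech duration sums word-interval lengths; the phonemic rate is the
#' phone count over the total recording duration. Per-phoneme-class duration
#' statistics (median, SD, IQR, CV, p10, p90; type-7 quantiles) are computed
#' over the phone durations of the six phoneme classes, and the fricative
#' duration kurtosis (Pearson, non-excess) is included. Syllable count is
#' approximated by the oral-vowel phone count (French syllable nuclei).
#' Intervals are half-open `[start, end)` in seconds.
#'
#' @param alignment List with `words` and `phones` interval data frames
#'   (`tmin`, `tmax`, plus `class`/`word` on the phone tier) and optionally
#'   `duration`.
#' @param pause_threshold_s Minimum silent gap counted as a pause (default
#'   0.15 s).
#' @param total_duration_s Recording duration used for the phonemic rate;
#'   defaults to `alignment$duration` (or the last word offset).
#' @return Named numeric vector validating against the catalog's temporal
#'   entries. Class statistics for absent classes are `NA`, counts 0.
#' @export
temporal_features <- function(alignment, pause_threshold_s = 0.15,
                              total_duration_s = NULL) {
  words <- alignment$words
  phones <- alignment$phones
  check_tier(words, "words")
  check_tier(phones, "phones")
  total_duration_s <- total_duration_s %||% alignment$duration %||%
    max(words$tmax, phones$tmax, 0)
  word_gaps <- if (nrow(words) > 1) words$tmin[-1] - words$tmax[-nrow(words)] else numeric(0)
  interword <- word_gaps[word_gaps >= pause_threshold_s]
  ## intra-word: gaps between consecutive phones of the same word
  intra <- numeric(0)
  if (nrow(phones) > 1 && !is.null(phones$word)) {
    for (w in unique(phones$word)) {
      ph <- phones[phones$word == w, , drop = FALSE]
      if (nrow(ph) > 1) {
        g <- ph$tmin[-1] - ph$tmax[-nrow(ph)]
        intra <- c(intra, g[g >= pause_threshold_s])
      }
    }
  }
  pauses <- c(interword, intra)
  durs <- phones$tmax - phones$tmin
  cls <- phones$class
  out <- c(
    pause_count = length(pauses),
    interword_pause_count = length(interword),
    intraword_pause_count = length(intra),
    pause_duration_median = if (length(pauses)) median(pauses) else NA_real_,
    pause_duration_sd = if (length(pauses) > 1) pop_sd(pauses) else NA_real_,
    total_speech_duration = sum(words$tmax - words$tmin),
    word_count = nrow(words),
    phone_count = nrow(phones),
    syllable_count = sum(cls == "oral_vowel"),
    phonemic_rate = nrow(phones) / total_duration_s
  )
  for (cl in PHONE_CLASSES) {
    d <- durs[cls == cl]
    stats <- if (length(d)) {
      c(length(d), median(d), if (length(d) > 1) pop_sd(d) else NA_real_,
        q7(d, 0.75) - q7(d, 0.25),
        if (length(d) > 1 && mean(d) > 0) pop_sd(d) / mean(d) else NA_real_,
        q7(d, 0.10), q7(d, 0.90))
    } else c(0, NA, NA, NA, NA, NA, NA)
    names(stats) <- sprintf("%s_%s", cl,
      c("count", "duration_median", "duration_sd", "duration_iqr",
        "duration_cv", "duration_p10", "duration_p90"))
    out <- c(out, stats)
  }
  out <- c(out, fricative_kurtosis = kurtosis_pearson(durs[cls == "fricative"]))
  out
}

#' Force a recording to an exact duration
#'
#' Standardizes audio to exactly `target_s` seconds: longer recordings are
#' truncated (excess removed from the end), shorter ones are padded with
#' trailing zeros (silence).
#'
#' @param audio An [audio_wave()]; must be non-empty.
#' @param target_s Target duration in seconds (default 60).
#' @return An [audio_wave()] of exactly `round(target_s * rate)` samples.
#' @export
standardize_duration <- function(audio, target_s = 60) {
  stopifnot(inherits(audio, "audio_wave"))
  n_target <- round(target_s * audio$sample_rate)
  x <- audio$samples
  mono <- !is.matrix(x)
  if (mono) x <- matrix(x, ncol = 1)
  if (nrow(x) == 0) stopf("cannot standardize empty audio")
  if (nrow(x) >= n_target) {
    x <- x[seq_len(n_target), , drop = FALSE]
  } else {
    x <- rbind(x, matrix(0, n_target - nrow(x), ncol(x)))
  }
  audio_wave(if (mono) x[, 1] else x, audio$sample_rate)
}

#' Extract the full feature vector of one recording
#'
#' Runs duration standardization then the spectral, phonatory and formant
#' extractors; for connected-speech tasks with an alignment, temporal
#' features are added. The result validates against the feature catalog.
#'
#' @param audio An [audio_wave()].
#' @param task Task code (`NEG`, `POS`, `SST`, `MPT`).
#' @param alignment Optional word/phone alignment (required for temporal
#'   features; ignored for MPT).
#' @param target_s Standardized duration (default 60 s; use `NULL` to skip).
#' @param cfg A [frame_config()].
#' @param pause_threshold_s Pause threshold for temporal features.
#' @param f0_range Pitch search range.
#' @return Named numeric feature vector.
#' @export
extract_features <- function(audio, task, alignment = NULL, target_s = 60,
                             cfg = frame_config(), pause_threshold_s = 0.15,
                             f0_range = c(60, 400)) {
  stopifnot(task %in% SPEECH_TASKS)
  if (!is.null(target_s)) audio <- standardize_duration(audio, target_s)
  out <- c(spectral_features(audio, cfg),
           phonatory_features(audio, f0_range),
           formant_features(audio, f0_range = f0_range))
  if (task != "MPT" && !is.null(alignment)) {
    dur <- if (!is.null(target_s)) target_s else
      audio_length(audio) / audio$sample_rate
    out <- c(out, temporal_features(alignment, pause_threshold_s,
                                    total_duration_s = dur))
  }
  validate_feature_vector(out[!is.na(out)], task)
  out
}

#' Maximum-phonation-time features across trials
#'
#' Given several sustained-phonation trials, selects the trial with the
#' longest voiced duration (earlier trial wins ties), extracts its
#' phonatory/spectral/formant features, and records the maximum phonation
#' duration in seconds. If every trial is unvoiced, all features are missing.
#'
#' @param trials List of [audio_wave()] objects (>= 1).
#' @param cfg A [frame_config()].
#' @param f0_range Pitch search range.
#' @return Named numeric vector including `max_phonation_time_s`; attribute
#'   `selected_trial` gives the chosen trial index.
#' @export
mpt_features <- function(trials, cfg = frame_config(), f0_range = c(60, 400)) {
  stopifnot(is.list(trials), length(trials) >= 1)
  voiced <- vapply(trials, function(tr) {
    ph <- phonatory_features(audio_mono(tr), f0_range)
    attr(ph, "voiced_duration_s") %||% 0
  }, 0)
  best <- which.max(voiced)   # which.max returns the earliest maximum
  if (voiced[best] <= 0) {
    out <- extract_features(trials[[1]], "MPT", target_s = NULL, cfg = cfg,
                            f0_range = f0_range)
    out["max_phonation_time_s"] <- NA_real_
    attr(out, "selected_trial") <- NA_integer_
    return(out)
  }
  out <- c(extract_features(trials[[best]], "MPT", target_s = NULL, cfg = cfg,
                            f0_range = f0_range),
           max_phonation_time_s = voiced[best])
  attr(out, "selected_trial") <- best
  out
}
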