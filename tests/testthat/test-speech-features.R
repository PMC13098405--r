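test_that("duration standardization truncates tails and pads with silence", {
  sr <- 8000
  long <- audio_wave(rnorm(63 * sr) * 0.1, sr)
  out <- standardize_duration(long, 60)
  expect_equal(length(out$samples), 60 * sr)
  expect_equal(out$samples, long$samples[1:(60 * sr)])
  short <- audio_wave(rnorm(57 * sr) * 0.1, sr)
  out2 <- standardize_duration(short, 60)
  expect_equal(length(out2$samples), 60 * sr)
  expect_true(all(out2$samples[(57 * sr + 1):(60 * sr)] == 0))
  exact <- audio_wave(rnorm(60 * sr) * 0.1, sr)
  expect_identical(standardize_duration(exact, 60)$samples, exact$samples)
  expect_error(standardize_duration(audio_wave(1, 8000)[c()], 60))
})

test_that("spectral features behave on canonical signals", {
  sr <- 16000
  t <- seq(0, 2, by = 1 / sr)
  tone <- audio_wave(sin(2 * pi * 440 * t), sr)
  sf <- spectral_features(tone)
  expect_lt(abs(sf[["spectral_centroid_mean"]] - 440), 25)
  ## digital silence: zero energy and zero flux
  sil <- spectral_features(audio_wave(numeric(sr), sr))
  expect_equal(sil[["rmse_mean"]], 0)
  expect_equal(sil[["spectral_flux_mean"]], 0)
  ## frame longer than signal rejected
  expect_error(spectral_features(audio_wave(rnorm(100), sr)), "longer than")
})

test_that("stationary noise has far lower flux than its modulated version", {
  sr <- 16000
  set.seed(11)
  noise <- rnorm(2 * sr)
  gate <- ifelse(sin(2 * pi * 2 * seq_along(noise) / sr) > 0, 1, 0)
  f_stat <- spectral_features(audio_wave(noise / max(abs(noise)), sr))
  f_am <- spectral_features(audio_wave(noise * gate / max(abs(noise)), sr))
  expect_lt(f_stat[["spectral_flux_mean"]], 0.10 * f_am[["spectral_flux_mean"]])
})

test_that("jitter and shimmer formulas match hand evaluation", {
  ## periods 10,12,10,12 ms: mean |diff| = 2, mean period = 11
  jm <- jitter_measures(c(10, 12, 10, 12) / 1000)
  expect_equal(jm[["jitter_local"]], 2 / 11, tolerance = 1e-12)
  ## constant sequences are perturbation-free
  jm0 <- jitter_measures(rep(0.01, 4))
  expect_equal(jm0[["jitter_local"]], 0)
  expect_equal(jm0[["jitter_rap"]], 0)
  sm0 <- shimmer_measures(rep(1, 6))
  expect_equal(unname(sm0), c(0, 0, 0))
  ## RAP hand case: interior deviations from 3-point means
  p <- c(10, 11, 13, 10, 12) / 1000
  rap_hand <- mean(abs(p[2:4] - (p[1:3] + p[2:4] + p[3:5]) / 3)) / mean(p)
  expect_equal(jitter_measures(p)[["jitter_rap"]], rap_hand, tolerance = 1e-12)
  ## APQ5/DDA hand case
  a <- c(1, 1.1, 0.9, 1.05, 0.95, 1.02)
  five <- sapply(3:4, function(i) mean(a[(i - 2):(i + 2)]))
  expect_equal(shimmer_measures(a)[["shimmer_apq5"]],
               mean(abs(a[3:4] - five)) / mean(a), tolerance = 1e-12)
  expect_equal(shimmer_measures(a)[["shimmer_dda"]],
               mean(abs(diff(diff(a)))) / mean(a), tolerance = 1e-12)
})

test_that("shimmer-only phonation recovers the setting with quiet jitter", {
  p <- phonation_params(jitter_level = 0, shimmer_level = 0.03, hnr_db = 40,
                        duration_s = 1.5)
  est <- vapply(1:10, function(s) {
    ph <- phonatory_features(generate_phonation_audio(p, seed = s))
    c(ph[["shimmer_local"]], ph[["jitter_local"]])
  }, c(0, 0))
  expect_lt(abs(median(est[1, ]) - 0.03) / 0.03, 0.30)
  expect_lt(median(est[2, ]), 0.005)
})

test_that("unvoiced audio yields missing phonatory and formant features", {
  sr <- 16000
  noise <- audio_wave(rnorm(sr) * 0.1, sr)
  ph <- phonatory_features(noise)
  expect_true(all(is.na(ph)))
  ff <- formant_features(noise)
  expect_true(all(is.na(ff)))
})

test_that("formant tracks recover synthetic resonances within 10%", {
  p <- phonation_params(duration_s = 1.5, hnr_db = 30, jitter_level = 0.005,
                        shimmer_level = 0.01)
  ff <- vapply(1:8, function(s)
    formant_features(generate_phonation_audio(p, seed = s)), numeric(7))
  med <- apply(ff, 1, median)
  expect_lt(abs(med[["f1_mean"]] - 700) / 700, 0.10)
  expect_lt(abs(med[["f2_mean"]] - 1200) / 1200, 0.10)
  expect_lt(abs(med[["f3_mean"]] - 2600) / 2600, 0.10)
})

test_that("a truly stationary vowel has tiny formant variability", {
  sr <- 16000
  t <- seq(0, 1.5, by = 1 / sr)
  x <- 0.4 * sin(2 * pi * 150 * t) + 0.25 * sin(2 * pi * 700 * t) +
    0.18 * sin(2 * pi * 1200 * t) + 0.12 * sin(2 * pi * 2600 * t)
  ff <- formant_features(audio_wave(x / max(abs(x)), sr))
  expect_lt(ff[["f2_cv"]], 0.02)
  expect_lt(ff[["f3_cv"]], 0.02)
})

test_that("doubling resonator damping raises the bandwidth estimate", {
  base <- phonation_params(duration_s = 1.5, hnr_db = 30,
                           jitter_level = 0.005, shimmer_level = 0.01)
  damp <- phonation_params(duration_s = 1.5, hnr_db = 30,
                           jitter_level = 0.005, shimmer_level = 0.01,
                           formant_bw_hz = c(80, 220, 280))
  b <- vapply(1:8, function(s) {
    f1 <- formant_features(generate_phonation_audio(base, seed = s))
    f2 <- formant_features(generate_phonation_audio(damp, seed = s))
    c(f1[["b2_mean"]], f2[["b2_mean"]], f1[["b3_mean"]], f2[["b3_mean"]])
  }, numeric(4))
  expect_gt(median(b[2, ]), median(b[1, ]))
  expect_gt(median(b[4, ]), median(b[3, ]))
})

test_that("temporal features match the worked interval example", {
  words <- data.frame(tmin = c(0, 0.7, 1.21), tmax = c(0.5, 1.2, 1.5),
                      label = c("w1", "w2", "w3"))
  phones <- data.frame(tmin = words$tmin, tmax = words$tmax,
                       label = c("a", "e", "i"), class = "oral_vowel",
                       word = words$label)
  tf <- temporal_features(list(words = words, phones = phones, duration = 2),
                          pause_threshold_s = 0.15)
  expect_equal(tf[["interword_pause_count"]], 1)
  expect_equal(tf[["pause_duration_median"]], 0.2, tolerance = 1e-12)
  expect_equal(tf[["total_speech_duration"]], 1.29, tolerance = 1e-12)
  expect_equal(tf[["syllable_count"]], 3)
  expect_equal(tf[["phonemic_rate"]], 3 / 2)
})

test_that("contiguous words give all-zero pause counts", {
  words <- data.frame(tmin = c(0, 0.5, 1.0), tmax = c(0.5, 1.0, 1.5),
                      label = c("w1", "w2", "w3"))
  phones <- data.frame(tmin = words$tmin, tmax = words$tmax, label = "a",
                       class = "oral_vowel", word = words$label)
  tf <- temporal_features(list(words = words, phones = phones))
  expect_equal(tf[["pause_count"]], 0)
  expect_equal(tf[["intraword_pause_count"]], 0)
})

test_that("phone-class duration statistics follow the type-7 quantile rule", {
  words <- data.frame(tmin = 0, tmax = 0.18, label = "w1")
  phones <- data.frame(tmin = c(0, 0.05, 0.11), tmax = c(0.05, 0.11, 0.18),
                       label = c("p", "t", "k"), class = "occlusive",
                       word = "w1")
  tf <- temporal_features(list(words = words, phones = phones))
  d <- c(0.05, 0.06, 0.07)
  expect_equal(tf[["occlusive_duration_median"]], 0.06, tolerance = 1e-12)
  expect_equal(tf[["occlusive_duration_iqr"]],
               unname(quantile(d, 0.75, type = 7) - quantile(d, 0.25, type = 7)),
               tolerance = 1e-12)
  expect_equal(tf[["occlusive_duration_p10"]],
               unname(quantile(d, 0.1, type = 7)), tolerance = 1e-12)
  expect_equal(tf[["occlusive_duration_p90"]],
               unname(quantile(d, 0.9, type = 7)), tolerance = 1e-12)
})

test_that("overlapping intervals are rejected with tier and index", {
  words <- data.frame(tmin = c(0, 0.4), tmax = c(0.5, 0.9), label = c("a", "b"))
  phones <- data.frame(tmin = 0, tmax = 0.9, label = "a",
                       class = "oral_vowel", word = "a")
  expect_error(temporal_features(list(words = words, phones = phones)),
               "tier 'words'.*index 2")
})

test_that("extracted vectors validate against the catalog per task", {
  al <- generate_alignment(10, pause_profile(), seed = 3)
  p <- phonation_params(duration_s = 1)
  audio <- generate_phonation_audio(p, seed = 1)
  fv <- extract_features(audio, "NEG", alignment = al, target_s = 2)
  expect_true(validate_feature_vector(fv[!is.na(fv)], "NEG"))
  ## temporal features are absent for the sustained-vowel task
  fv_mpt <- extract_features(audio, "MPT", target_s = NULL)
  expect_false(any(grepl("pause", names(fv_mpt))))
  expect_true(validate_feature_vector(fv_mpt[!is.na(fv_mpt)], "MPT"))
})

test_that("MPT selects the longest voiced trial, ties to the earlier one", {
  p_short <- phonation_params(duration_s = 0.8)
  p_long <- phonation_params(duration_s = 1.4)
  t1 <- generate_phonation_audio(p_short, seed = 1)
  t2 <- generate_phonation_audio(p_long, seed = 2)
  out <- mpt_features(list(t1, t2))
  expect_equal(attr(out, "selected_trial"), 2L)
  expect_gt(out[["max_phonation_time_s"]], 1.0)
  ## single trial: that trial
  out1 <- mpt_features(list(t1))
  expect_equal(attr(out1, "selected_trial"), 1L)
  ## tie: identical trials -> earlier index
  out_tie <- mpt_features(list(t1, t1))
  expect_equal(attr(out_tie, "selected_trial"), 1L)
  ## all-unvoiced trials flagged missing
  noise <- audio_wave(rnorm(16000) * 0.05, 16000)
  out_uv <- mpt_features(list(noise))
  expect_true(is.na(out_uv[["max_phonation_time_s"]]))
})

test_that("feature extraction is deterministic for fixed audio and settings", {
  p <- phonation_params(duration_s = 1)
  audio <- generate_phonation_audio(p, seed = 5)
  expect_identical(extract_features(audio, "MPT", target_s = NULL),
                   extract_features(audio, "MPT", target_s = NULL))
})
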