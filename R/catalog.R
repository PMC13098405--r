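PHONE_CLASSES <- c("occlusive", "fricative", "nasal", "liquid",
                   "semivowel", "oral_vowel")
SPEECH_TASKS <- c("NEG", "POS", "SST", "MPT")

#' The typed feature catalog
#'
#' Enumerates every feature the extraction stage can emit, with its family
#' (spectral, phonatory, formant, temporal), the summary statistic it carries,
#' and the tasks it applies to. Temporal (alignment-derived) features do not
#' apply to the sustained-vowel task (MPT), which instead carries the maximum
#' phonation duration.
#'
#' @param fricative_kurtosis One of `"duration"` (kurtosis of fricative phone
#'   durations, the default) or `"spectral"` (mean spectral kurtosis within
#'   fricative intervals); the published feature name is ambiguous between the
#'   two readings, so both are available behind this switch.
#' @return A data frame with columns `name`, `family`, `statistic`, `tasks`
#'   (comma-separated applicable tasks).
#' @export
feature_catalog <- function(fricative_kurtosis = c("duration", "spectral")) {
  fricative_kurtosis <- match.arg(fricative_kurtosis)
  all_tasks <- paste(SPEECH_TASKS, collapse = ",")
  speech_tasks <- "NEG,POS,SST"
  row <- function(name, family, statistic, tasks) {
    data.frame(name = name, family = family, statistic = statistic,
               tasks = tasks, stringsAsFactors = FALSE)
  }
  entries <- list(
    row(c("spectral_centroid_mean", "spectral_rolloff_mean",
          "spectral_flux_mean", "rmse_mean"), "spectral", "mean", all_tasks),
    row(c("spectral_centroid_sd", "spectral_rolloff_sd",
          "spectral_flux_sd", "rmse_sd"), "spectral", "SD", all_tasks),
    row(sprintf("spectral_contrast_mean_%d", 0:5), "spectral", "mean", all_tasks),
    row(sprintf("spectral_contrast_sd_%d", 0:5), "spectral", "SD", all_tasks),
    row(sprintf("chroma_mean_%d", 0:11), "spectral", "mean", all_tasks),
    row(sprintf("mfcc_mean_%d", 1:13), "spectral", "mean", all_tasks),
    row(sprintf("mfcc_sd_%d", 1:13), "spectral", "SD", all_tasks),
    row(sprintf("dmfcc_mean_%d", 1:13), "spectral", "mean", all_tasks),
    row(sprintf("dmfcc_sd_%d", 1:13), "spectral", "SD", all_tasks),
    row(c("f0_mean", "f0_max", "jitter_local", "jitter_rap", "shimmer_local",
          "shimmer_apq5", "shimmer_dda", "hnr_mean"),
        "phonatory", "mean", all_tasks),
    row(c("f0_sd", "hnr_sd"), "phonatory", "SD", all_tasks),
    row(c("f1_mean", "f2_mean", "f3_mean", "b2_mean", "b3_mean"),
        "formant", "mean", all_tasks),
    row(c("f2_cv", "f3_cv"), "formant", "CV", all_tasks),
    row(c("pause_count", "interword_pause_count", "intraword_pause_count",
          "word_count", "phone_count", "syllable_count"),
        "temporal", "count", speech_tasks),
    row("pause_duration_median", "temporal", "median", speech_tasks),
    row("pause_duration_sd", "temporal", "SD", speech_tasks),
    row("total_speech_duration", "temporal", "mean", speech_tasks),
    row("phonemic_rate", "temporal", "rate", speech_tasks),
    row(sprintf("%s_count", PHONE_CLASSES), "temporal", "count", speech_tasks),
    row(sprintf("%s_duration_median", PHONE_CLASSES), "temporal", "median", speech_tasks),
    row(sprintf("%s_duration_sd", PHONE_CLASSES), "temporal", "SD", speech_tasks),
    row(sprintf("%s_duration_iqr", PHONE_CLASSES), "temporal", "IQR", speech_tasks),
    row(sprintf("%s_duration_cv", PHONE_CLASSES), "temporal", "CV", speech_tasks),
    row(sprintf("%s_duration_p10", PHONE_CLASSES), "temporal", "p10", speech_tasks),
    row(sprintf("%s_duration_p90", PHONE_CLASSES), "temporal", "p90", speech_tasks),
    row("fricative_kurtosis",
        if (fricative_kurtosis == "duration") "temporal" else "spectral",
        "mean", speech_tasks),
    row("max_phonation_time_s", "phonatory", "mean", "MPT")
  )
  cat <- do.call(rbind, entries)
  stopifnot(!anyDuplicated(cat$name))
  cat
}

catalog_for_task <- function(task, catalog = feature_catalog()) {
  stopifnot(task %in% SPEECH_TASKS)
  keep <- vapply(strsplit(catalog$tasks, ","), function(t) task %in% t, TRUE)
  catalog[keep, , drop = FALSE]
}

#' French phone to phoneme-class mapping
#'
#' Maps SAMPA-style French phone labels to the six phoneme classes used by
#' the temporal features (occlusive, fricative, nasal, liquid, semivowel,
#' oral vowel). Shipped as an editable CSV resource.
#'
#' @param path Optional path to an alternative mapping CSV (`phone`, `class`).
#' @return Named character vector: phone label -> class.
#' @export
phone_class_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "phone_classes.csv",
                                package = "speechstrat")
  map <- read.csv(path, stringsAsFactors = FALSE)
  assert_cols(map, c("phone", "class"), "phone class map")
  bad <- setdiff(unique(map$class), PHONE_CLASSES)
  if (length(bad)) stopf("unknown phoneme class(es): %s", paste(bad, collapse = ", "))
  setNames(map$class, map$phone)
}

#' Validate a feature vector against the catalog
#'
#' Checks that every name is a catalog entry applicable to the task, counts
#' are non-negative integers and durations non-negative (missing values are
#' allowed: absent/unvoiced features are explicit `NA`s, never zeros).
#'
#' @param values Named numeric vector of features.
#' @param task Task code the vector was extracted from.
#' @param catalog A [feature_catalog()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_feature_vector <- function(values, task, catalog = feature_catalog()) {
  tc <- catalog_for_task(task, catalog)
  unknown <- setdiff(names(values), tc$name)
  if (length(unknown)) {
    stopf("feature(s) not in the %s catalog: %s", task,
          paste(head(unknown, 5), collapse = ", "))
  }
  counts <- intersect(names(values), tc$name[tc$statistic == "count"])
  cv <- values[counts]
  cv <- cv[!is.na(cv)]
  if (length(cv) && (any(cv < 0) || any(abs(cv - round(cv)) > 1e-9))) {
    stopf("count features must be non-negative integers")
  }
  dur <- grep("duration|max_phonation", names(values), value = TRUE)
  dv <- values[dur][!is.na(values[dur])]
  if (length(dv) && any(dv < -1e-12)) stopf("durations must be non-negative")
  invisible(TRUE)
}
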