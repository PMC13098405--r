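#' Group signature: class-conditional feature shifts for the generator
#'
#' A signature says, for each diagnostic group, which features are shifted
#' (in SD units, signed: positive = increased relative to healthy controls)
#' plus optional correlated feature blocks and a residual noise SD.
#'
#' @param feature_shifts Named list: group label -> named numeric vector of
#'   signed shifts (feature name -> shift in SD units).
#' @param correlation_blocks List of lists with fields `features` (character
#'   vector of feature names) and `rho` (intra-block correlation, |rho| < 1).
#' @param noise_sd Residual standard deviation (default 1).
#' @return Object of class `group_signature`.
#' @export
group_signature <- function(feature_shifts, correlation_blocks = list(),
                            noise_sd = 1) {
  stopifnot(is.list(feature_shifts))
  for (bl in correlation_blocks) {
    if (is.null(bl$features) || is.null(bl$rho)) {
      stopf("each correlation block needs fields 'features' and 'rho'")
    }
    if (abs(bl$rho) >= 1) stopf("|rho| of a correlation block must be < 1")
  }
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  structure(list(feature_shifts = feature_shifts,
                 correlation_blocks = correlation_blocks,
                 noise_sd = noise_sd),
            class = "group_signature")
}

signature_features <- function(sig) {
  unique(c(unlist(lapply(sig$feature_shifts, names), use.names = FALSE),
           unlist(lapply(sig$correlation_blocks, `[[`, "features"),
                  use.names = FALSE)))
}

#' Default group signature following the published direction table
#'
#' Encodes, per diagnostic group, the Increased/Decreased vocal-biomarker
#' directions reported for each pathology (physiotype-level directions are
#' applied to every group of that physiotype, pathotype-specific directions
#' on top). Magnitudes are not published; the default effect size is 0.8 SD
#' (medium-to-large), configurable.
#'
#' @param effect_size Absolute shift in SD units applied to every signed
#'   feature (default 0.8).
#' @param noise_sd Residual SD.
#' @return A [group_signature()].
#' @export
default_group_signature <- function(effect_size = 0.8, noise_sd = 1) {
  sgn <- function(inc, dec) {
    c(setNames(rep(1, length(inc)), inc), setNames(rep(-1, length(dec)), dec))
  }
  physio <- list(
    AD = sgn(
      inc = c("total_speech_duration", "fricative_duration_median",
              "nasal_duration_median", "f3_mean", "spectral_flux_mean",
              "spectral_flux_sd"),
      dec = c("semivowel_duration_sd", "jitter_local", "jitter_rap",
              "hnr_mean", "fricative_kurtosis", "b2_mean",
              "spectral_centroid_sd", "spectral_rolloff_sd")),
    FTLD = sgn(
      inc = c("pause_count", "interword_pause_count", "occlusive_count",
              "phone_count", "dmfcc_mean_3", "spectral_contrast_mean_1",
              "chroma_mean_0", "chroma_mean_8", "chroma_mean_10"),
      dec = c("semivowel_duration_p90", "hnr_sd", "shimmer_local",
              "shimmer_apq5")),
    HC = numeric(0)
  )
  patho <- list(
    "aAD" = sgn(
      inc = c("nasal_count", "nasal_duration_iqr", "liquid_duration_iqr",
              "chroma_mean_7", "rmse_mean"),
      dec = c("fricative_count", "fricative_duration_iqr", "f3_cv",
              "b3_mean")),
    "lvPPA-AD" = sgn(
      inc = c("occlusive_duration_median", "chroma_mean_3", "chroma_mean_5"),
      dec = c("syllable_count", "oral_vowel_count", "f0_max",
              "spectral_contrast_mean_0")),
    "bvFTLD" = sgn(
      inc = c("nasal_duration_median", "semivowel_duration_median",
              "f3_cv"),
      dec = c("nasal_count", "b3_mean", "spectral_contrast_mean_0",
              "chroma_mean_1")),
    "lvPPA-FTLD" = sgn(
      inc = c("pause_duration_median", "pause_duration_sd",
              "dmfcc_mean_1", "dmfcc_mean_4", "spectral_centroid_mean"),
      dec = c("phonemic_rate", "dmfcc_mean_12", "chroma_mean_5")),
    "nfvPPA-FTLD" = sgn(
      inc = c("intraword_pause_count", "liquid_duration_median",
              "occlusive_duration_median", "f0_mean",
              "spectral_contrast_mean_4", "shimmer_dda"),
      dec = c("dmfcc_mean_4", "dmfcc_mean_12")),
    "svPPA-FTLD" = sgn(
      inc = c("semivowel_duration_cv", "dmfcc_mean_5", "f2_cv"),
      dec = c("semivowel_duration_p10", "oral_vowel_duration_sd",
              "fricative_count", "spectral_flux_mean")),
    "HC" = numeric(0)
  )
  shifts <- lapply(GROUP_LABELS, function(g) {
    s <- physio[[physiotype_of(g)]]
    p <- patho[[g]] %||% numeric(0)
    for (nm in names(p)) s[nm] <- p[nm]  # pathotype-specific overrides/extends
    if (!length(s)) return(setNames(numeric(0), character(0)))
    s * effect_size
  })
  names(shifts) <- GROUP_LABELS
  group_signature(shifts, noise_sd = noise_sd)
}

#' Generate per-task feature tables with the signature's structure
#'
#' Feature `j` for a participant of group `g` is drawn
#' `Normal(shift[g, j], noise_sd)`; features absent from the signature are
#' pure noise. Correlated blocks are imposed through a common-factor
#' construction (`x_j = sqrt(rho) z_block + sqrt(1 - rho) e_j + shift`),
#' giving intra-block correlation `rho`. Class imbalance follows the cohort.
#'
#' @param cohort Participant table from [generate_cohort()].
#' @param sig A [group_signature()], or a named list of signatures (one per
#'   task) when tasks carry different signal.
#' @param n_features Total feature count per task (>= the number of signed
#'   features); unnamed filler features are noise named `noise_###`.
#' @param seed Integer seed.
#' @param tasks Task codes to generate (default all four).
#' @return Named list (one data frame per task): `participant_id` + features.
#' @export
generate_feature_table <- function(cohort, sig = default_group_signature(),
                                   n_features = NULL,
                                   seed = 1L,
                                   tasks = SPEECH_TASKS) {
  assert_cols(cohort, c("participant_id", "group"), "cohort")
  per_task_sig <- if (inherits(sig, "group_signature")) {
    setNames(rep(list(sig), length(tasks)), tasks)
  } else {
    stopifnot(all(tasks %in% names(sig)))
    sig[tasks]
  }
  out <- list()
  for (ti in seq_along(tasks)) {
    task <- tasks[ti]
    s <- per_task_sig[[task]]
    shift_named <- unique(unlist(lapply(s$feature_shifts, names),
                                 use.names = FALSE))
    for (bl in s$correlation_blocks) {
      miss <- setdiff(bl$features, shift_named)
      if (length(miss)) stopf("correlation block references unknown feature(s): %s",
                              paste(miss, collapse = ", "))
    }
    named <- signature_features(s)
    nf <- n_features %||% (length(named) + 10L)
    if (nf < length(named)) {
      stopf("n_features (%d) < number of signature features (%d)", nf, length(named))
    }
    feat_names <- c(named, sprintf("noise_%03d", seq_len(nf - length(named))))
    set.seed(child_seed(seed, ti))
    n <- nrow(cohort)
    x <- matrix(rnorm(n * nf, 0, s$noise_sd), n, nf,
                dimnames = list(NULL, feat_names))
    ## common-factor correlation within blocks
    for (bl in s$correlation_blocks) {
      z <- rnorm(n, 0, s$noise_sd)
      rho <- bl$rho
      for (f in bl$features) {
        x[, f] <- sqrt(abs(rho)) * sign(rho) * z + sqrt(1 - abs(rho)) * x[, f]
      }
    }
    ## signed class-conditional shifts
    for (g in unique(cohort$group)) {
      rows <- cohort$group == g
      shifts <- s$feature_shifts[[g]]
      for (f in names(shifts)) {
        if (!f %in% feat_names) stopf("shift references unknown feature '%s'", f)
        x[rows, f] <- x[rows, f] + shifts[f]
      }
    }
    out[[task]] <- data.frame(participant_id = cohort$participant_id, x,
                              check.names = FALSE, stringsAsFactors = FALSE)
  }
  out
}
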