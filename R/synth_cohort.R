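GROUP_LABELS <- c("aAD", "lvPPA-AD", "bvFTLD", "lvPPA-FTLD",
                  "svPPA-FTLD", "nfvPPA-FTLD", "HC")

#' Map a diagnostic group to its physiotype
#'
#' The physiotype is the underlying etiological pathology: amnestic AD and
#' logopenic PPA with AD pathology map to AD; the behavioural and PPA
#' variants with FTLD pathology map to FTLD; healthy controls stay HC. The
#' mapping is a pure function of the group label.
#'
#' @param group Character vector of group labels.
#' @return Character vector of physiotypes (`"AD"`, `"FTLD"`, `"HC"`).
#' @export
physiotype_of <- function(group) {
  map <- c("aAD" = "AD", "lvPPA-AD" = "AD",
           "bvFTLD" = "FTLD", "lvPPA-FTLD" = "FTLD",
           "svPPA-FTLD" = "FTLD", "nfvPPA-FTLD" = "FTLD",
           "HC" = "HC")
  unknown <- setdiff(unique(group), names(map))
  if (length(unknown)) stopf("unknown group label(s): %s", paste(unknown, collapse = ", "))
  unname(map[group])
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate the published cohort structure: seven diagnostic groups
#' with the study's group sizes and (where printed) per-group age
#' distributions. Ages not printed in the source material and the per-group
#' female fractions use realistic fill-ins, documented in the methods
#' vignette.
#'
#' @param n_per_group Either a single count applied to every group, or a
#'   named vector with one count per group label. Every count must be >= 2.
#' @param group_labels Ordered group labels (fixed seven-label set by default).
#' @param age_model Data frame `group`, `mean`, `sd` (years).
#' @param sex_model Named vector of female fractions per group.
#' @param discordance_rate Fraction of patients (never controls) flagged as
#'   clinicopathologically discordant, in `[0, 1]`.
#' @param seed Integer seed making the cohort reproducible.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c("aAD" = 30, "lvPPA-AD" = 19,
                                        "bvFTLD" = 21, "lvPPA-FTLD" = 11,
                                        "svPPA-FTLD" = 13, "nfvPPA-FTLD" = 14,
                                        "HC" = 64),
                        group_labels = GROUP_LABELS,
                        age_model = default_age_model(),
                        sex_model = setNames(rep(0.5, 7), GROUP_LABELS),
                        discordance_rate = 0.15,
                        seed = 1L) {
  if (length(n_per_group) == 1 && is.null(names(n_per_group))) {
    n_per_group <- setNames(rep(n_per_group, length(group_labels)), group_labels)
  }
  if (!setequal(names(n_per_group), group_labels)) {
    stopf("n_per_group must be named with exactly the group labels")
  }
  n_per_group <- n_per_group[group_labels]
  if (any(n_per_group < 2)) stopf("n_per_group must be >= 2 for every group")
  if (discordance_rate < 0 || discordance_rate > 1) {
    stopf("discordance_rate must be within [0, 1]")
  }
  structure(list(n_per_group = n_per_group, group_labels = group_labels,
                 age_model = age_model, sex_model = sex_model,
                 discordance_rate = discordance_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_age_model <- function() {
  data.frame(
    group = GROUP_LABELS,
    mean  = c(72.0, 70.4, 67.5, 69.0, 63.5, 64.2, 70.0),
    sd    = c(3.6, 3.7, 6.5, 5.0, 6.1, 3.8, 6.0),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic participant table
#'
#' Draws one row per participant: group, physiotype (a deterministic function
#' of group), age (per-group normal), sex (Bernoulli on the per-group female
#' fraction), and a discordance flag set for exactly
#' `round(discordance_rate * n_patients)` patients (round-half-up), never for
#' healthy controls.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame `participant_id`, `group`, `physiotype`, `age`, `sex`,
#'   `discordant`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- rep(spec$group_labels, times = spec$n_per_group)
  n <- length(groups)
  am <- spec$age_model[match(groups, spec$age_model$group), ]
  age <- round(rnorm(n, am$mean, am$sd), 1)
  age <- pmax(age, 40)
  female <- rbinom(n, 1, spec$sex_model[groups]) == 1
  cohort <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = groups,
    physiotype = physiotype_of(groups),
    age = age,
    sex = ifelse(female, "F", "M"),
    discordant = FALSE,
    stringsAsFactors = FALSE
  )
  patients <- which(cohort$physiotype != "HC")
  n_disc <- round_half_up(spec$discordance_rate * length(patients))
  if (n_disc > 0) {
    cohort$discordant[sample(patients, n_disc)] <- TRUE
  }
  cohort
}
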