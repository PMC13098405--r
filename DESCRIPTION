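Package: speechstrat
Title: Speech-Based Etiological Stratification of Alzheimer's Disease and
    Frontotemporal Lobar Degeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for etiological stratification of
    neurodegenerative disease from standardized speech recordings. Provides a
    synthetic cohort generator (participants, phonation audio, forced-alignment
    tiers, per-task feature tables), acoustic/phonatory/formant/temporal feature
    extraction, leakage-guarded preprocessing (train-only z-scoring, iterative
    VIF and pairwise-correlation filtering), participant-level stratified
    splitting with repeated stratified cross-validation and in-fold
    oversampling, model selection by Bayesian correlated t-tests with a region
    of practical equivalence, hierarchical and flat classification frameworks
    plus stacked generalization from out-of-fold probabilities, a full held-out
    metric suite with bootstrap confidence intervals and discordance
    reclassification, and an interpretation layer (Shapley attributions,
    pairwise Mann-Whitney effect-size matrices with false-discovery-rate
    control, demographic confound checks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    ranger,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
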