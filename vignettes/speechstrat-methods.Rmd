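---
title: "Speech-based etiological stratification: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech-based etiological stratification: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`speechstrat` re-implements, as a tested pipeline, a speech-based analysis
for separating the two major etiologies behind early neurodegenerative
cognitive complaints — Alzheimer's disease (AD) and frontotemporal lobar
degeneration (FTLD) — from four standardized speech tasks: two
autobiographical monologues (negative, NEG, and positive, POS, valence), a
sentence-repetition span task (SST), and a maximum phonation time task
(MPT, a sustained /a/). Two levels of label are used throughout:

* **physiotype** — the underlying pathology (AD, FTLD, or healthy control),
  independent of clinical presentation;
* **pathotype** — the crossed clinical-phenotype-by-pathology label
  (amnestic AD, lvPPA-AD, bvFTLD, lvPPA-FTLD, svPPA-FTLD, nfvPPA-FTLD, HC),
  where lvPPA/nfvPPA/svPPA are the logopenic, non-fluent and semantic
  variants of primary progressive aphasia.

Because no clinical recordings are distributable, the package ships a
synthetic cohort generator that reproduces the statistical *structure* the
analysis assumes — group sizes, demographics, signed class-conditional
feature shifts, collinearity, class imbalance, discordant cases — so every
downstream stage is testable end to end without any data download.

# The synthetic cohort

`cohort_spec()` defaults to the seven-group structure of the motivating
study: 30 aAD, 19 lvPPA-AD, 21 bvFTLD, 11 lvPPA-FTLD, 13 svPPA-FTLD,
14 nfvPPA-FTLD, 64 controls (N = 172). Ages are drawn per group from
normal distributions; the published per-group ages are used where printed
(aAD 72.0 ± 3.6, lvPPA-AD 70.4 ± 3.7, svPPA-FTLD 63.5 ± 6.1, nfvPPA-FTLD
64.2 ± 3.8 years) and realistic fill-ins otherwise (bvFTLD 67.5 ± 6.5,
lvPPA-FTLD 69.0 ± 5.0, HC 70.0 ± 6.0; female fraction 0.5 throughout —
per-group sex ratios were not available to this implementation). A fraction
of patients (default 15%) is flagged *clinicopathologically discordant* —
their clinical syndrome disagreed with at least one biomarker modality;
controls are never flagged. Counts round half-up.

`default_group_signature()` encodes, per group, which features are
increased or decreased relative to controls, following the published
direction table (physiotype-level directions apply to both groups of that
physiotype; pathotype-specific directions are added on top). The published
material gives directions, not magnitudes, so every signed feature is
shifted by ±0.8 SD by default — a medium-to-large effect consistent with
the reported effect-size range — and the magnitude is a single
configurable number. Correlated feature blocks are imposed through a
common-factor construction (`x_j = sqrt(rho) z + sqrt(1-rho) e_j`), and
unsigned features are pure noise, so the collinearity filter and the
no-signal null are both exercisable.

Where column boundaries in the published direction table were ambiguous in
the source text, the default signature resolves them editorially; the
signature is an ordinary editable object and the generator's fidelity
contract is to the `group_signature` it is given, not to any particular
reading of that table.

# Synthetic phonation

`generate_phonation_audio()` synthesizes a sustained vowel as a
Rosenberg-style glottal pulse train (open phase = 0.6 of the *nominal*
period) filtered through three second-order resonators (defaults 700,
1200, 2600 Hz with 80/110/140 Hz bandwidths, an /a/-like configuration),
differentiated for lip radiation, plus white noise calibrated so the
harmonic-to-noise power ratio equals the requested HNR. Period and
amplitude perturbations are Gaussian, scaled by `sqrt(pi)/2` so that the
*expected* local jitter and shimmer equal the requested levels. Two
details matter and were found the hard way:

* pulses are placed at fractional sample positions (linear interpolation);
  integer quantization alone creates a ~0.4% jitter floor at 16 kHz;
* the pulse shape is constant across cycles; scaling the open phase with
  each jittered period moves every cycle's acoustic center by a fraction
  of the perturbation and smears the measured jitter by roughly half.

The synthesis contract is parameter recovery, not waveform identity: the
recovery suite checks that extracted jitter/shimmer/HNR are monotone in
the generator settings and within ±30% (perturbations) / ±3 dB (HNR) at
mid-range.

# Feature extraction

All features live in a typed catalog (`feature_catalog()`): family
(spectral / phonatory / formant / temporal), summary statistic, and task
applicability (temporal features require an alignment and do not apply to
MPT). Recordings are standardized to exactly 60 s — truncated from the
end, or padded with trailing silence — before extraction.

**Frames.** 25 ms Hann windows with 10 ms hop; pitch analysis uses 40 ms
frames. F0 search range 60–400 Hz. These values are common speech-analysis
conventions; the motivating study does not state its own.

**Spectral.** Centroid, rolloff (0.85), per-band spectral contrast (six
octave bands, top/bottom 20% peak-valley log ratio), 12 chroma bins, 13
MFCCs and delta-MFCCs from a 26-filter mel bank, and frame RMS energy,
each reduced to mean and SD. *Spectral flux* is defined as the L2
difference of consecutive moving-average-smoothed (15 frames) octave-band
log-magnitude spectra with a relative floor: on the log scale, genuine
level and spectral change dominates the stochastic frame-to-frame
fluctuation of stationary signals by more than an order of magnitude,
which is the discriminating property the flux feature is meant to carry.
Digital silence yields zero RMS and zero flux.

**Phonatory.** Voicing and F0 per frame by autocorrelation (unbiased
overlap normalization, parabolic interpolation, octave preference for the
shortest near-maximal lag; voicing threshold 0.45). HNR per voiced frame is
`10 log10(r/(1-r))` from the normalized autocorrelation peak `r`, capped at
40 dB to avoid infinities on near-perfect periodicity, summarized as mean
and SD. Cycle-level periods come from narrowband anchor peaks refined by
per-cycle waveform cross-correlation (the lag that best aligns one cycle
with the next); cycle amplitudes are the narrowband peak heights. Jitter
(local, RAP), shimmer (local, APQ5, DDA) follow the standard
perturbation-quotient formulas. If no voiced frame exists, every phonatory
feature is an explicit missing value — never zero.

A known cross-talk: strong jitter inflates the shimmer estimate (period
perturbation modulates the narrowband envelope). The recovery suite varies
one perturbation at a time; mixed-perturbation shimmer readings should be
interpreted as upper bounds.

**Formants.** Autocorrelation-method linear prediction (order 18 at
16 kHz) with a Gaussian lag window (~70 Hz kernel) that collapses the
harmonic line structure into the spectral envelope; poles with bandwidth
< 1.2 kHz and frequency in (150 Hz, 0.95 Nyquist) are candidates, the three
lowest are F1–F3. Bandwidth estimates are inflated by roughly the kernel
width but remain monotone in the true resonance damping, which is the
property the B2/B3 features carry. (The published abbreviation for B2/B3
is ambiguous between formant bandwidths and centroid/rolloff-derived
bands; this package implements formant bandwidths.)

**Temporal.** From word/phone alignment tiers (Praat TextGrid, long or
short dialect; intervals half-open `[start, end)`, times taken verbatim):
a pause is any silent gap ≥ 150 ms (configurable; the motivating study
never defines "pause"); inter-word pauses are gaps between word intervals,
intra-word pauses are gaps between phones inside one word. Phone durations
are summarized per phoneme class (occlusive, fricative, nasal, liquid,
semivowel, oral vowel; the French phone-to-class map ships as an editable
CSV). Quantiles are type-7 (linear interpolation), which matters for IQR,
p10 and p90. Syllable count is approximated by the oral-vowel count
(French nuclei). "Fricative kurtosis" is implemented as the Pearson
kurtosis of fricative phone durations, with a catalog switch for the
spectral reading of that name. MPT keeps the trial with the longest voiced
duration (earlier trial on ties) and records it in seconds.

# Leakage-guarded preprocessing

All preprocessing is fit on training rows only and frozen: median
imputation of missing features, z-scoring (population SD, matching common
scaler behavior; constant features dropped and recorded), then iterative
multicollinearity filtering. The filter recomputes pairwise Pearson
correlations and VIFs after *every single removal*, removing the violating
feature (VIF > 5 or in a pair with |r| > 0.95) with the highest mean
absolute correlation to all others; ties break lexicographically. VIF is
computed by regressing each feature on the rest (QR-based), with a large
finite value and a recorded warning when the design is rank-deficient.
Since Pearson r and VIF are scale-invariant, the impute → scale → filter
order is benign; it is fixed and documented. Idempotence and
threshold-satisfaction of survivors are tested properties.

# Partitioning, folds, and imbalance

Splitting is participant-level (all four recordings of a participant stay
on one side), stratified by class × age group × sex. Age bins are
{<65, 65–75, >75} — the study says "age group" without bins. Cells
contribute `round(test_frac · n)` (half-up) test members; singleton cells
stay in training with a warning. Model selection uses stratified repeated
5-fold cross-validation (5 repetitions by default); within each fold's
training side only, minority classes are randomly oversampled to the
majority count (alternatives for sensitivity analyses: inverse-frequency
class weights, or none). Oversampling refuses rows not tagged as
fold-training rows, which turns a leakage bug into an error.

# Model selection

Seven candidate algorithms are trained per task — elastic-net logistic
regression (glmnet), RBF SVM (e1071), random forest and extremely
randomized trees (ranger), extreme gradient boosting and a classic
shallow-tree gradient-boosting configuration (both via xgboost, with
distinct search spaces), and k-nearest neighbours (e1071::gknn). Every
candidate exposes class probabilities. Hyperparameters are drawn from
per-candidate randomized spaces (default budget 8 settings per candidate
per fold, chosen so a full default experiment completes comfortably on a
single CPU; configurable) and scored on an inner stratified split of the
fold-training rows.

Candidates are compared with a **Bayesian correlated t-test** on the
paired per-fold macro-OvR AUCs: the posterior of the mean difference is
Student-t with location `mean(d)`, scale `sqrt((1/m + rho) var(d))` and
`m-1` degrees of freedom, where `m` is the number of folds and
`rho = 1/(k-1)` is the test/train size-ratio correction for k-fold
cross-validation (0.25 for 5-fold) — the standard correction for
correlated CV estimates, which the motivating study names but does not
parameterize. Posterior mass is split below/inside/above a region of
practical equivalence (ROPE) of ±0.01 AUC. A candidate wins outright if
its posterior probability of beating *every* competitor exceeds 0.95;
among a practically-equivalent top set, higher mean Cohen's kappa then
lower log loss decide; otherwise the decision is flagged "undecided" and
the highest-mean-AUC candidate is returned with the full trace.
Zero-variance difference vectors resolve to point masses, selection is
invariant to candidate ordering, and antisymmetry/mass-conservation/ROPE
monotonicity are tested properties.

# Frameworks

* **Flat**: one multi-class model per level (physiotype or pathotype);
  prediction is the argmax class probability, no custom threshold.
* **Hierarchical**: a physiotype gate followed by per-branch pathotype
  classifiers trained only on rows whose *true* physiotype matches the
  branch. A wrong gate decision necessarily yields a wrong pathotype —
  the **propagation error** is the fraction of samples with a wrong gate
  decision (for flat models the analogous quantity is the fraction of
  predictions mapping to the wrong physiotype). Pathotype accuracy is
  structurally bounded by gate accuracy, and the bound is asserted on
  every evaluation.
* **Stacking**: the per-task winners produce out-of-fold (OOF) class
  probabilities via 5-fold CV over the training participants; the
  concatenated OOF blocks train a meta-model chosen among SVM, logistic
  regression, random forest and gradient boosting by the same selection
  machinery. Test-time meta-features come from the base winners refit on
  the full training set (standard stacking practice; the study does not
  state this step explicitly). Participants missing a task are excluded
  with a logged manifest. A construction audit records, for every
  (participant, fold), that the predicting base model never trained on
  that participant; the audit must be empty of violations.

Healthy controls are included as a third gate class by default (the
published contrast matrices include HC); `include_hc = FALSE` restores the
patients-only AD-vs-FTLD framing. Stacking is built per classification
level.

# Evaluation

`compute_metrics()` reports accuracy, macro precision/recall/F1
(zero-division → 0, counted), macro one-vs-rest AUC (rank-based, midranks
for ties; classes absent from truth are excluded with a warning), log loss
(probabilities clipped at 1e-15), Cohen's kappa, multiclass Matthews
correlation, and macro-OvR FPR/FNR. Bootstrap 95% CIs (percentile,
default 1000 replicates) resample *participants*, so all recordings of a
participant move together, consistent with the split unit; degenerate
replicates are skipped and counted. The **reclassification rate** — among
held-out discordant patients, the fraction whose predicted etiology
matches the biomarker-confirmed one — is reported as descriptive and
exploratory, with a per-case audit table; zero discordant cases yield an
explicit missing value, never 0.

# Interpretation

Pairwise **Mann-Whitney** tests per feature × group pair × task use the
tie-corrected normal approximation; the effect size is `r = |Z|/sqrt(N)`
on the *uncorrected* Z (so the worked small-sample values come out
exactly), while p-values use exact enumeration for small untied samples
and the continuity-corrected approximation otherwise. Benjamini-Hochberg
FDR runs across features within each (pair × task) family, matching the
per-cell significance rates of the published contrast figure; matrix cells
carry the mean effect size over all features (the source does not say
whether significant features only are averaged; all features was chosen
and is flagged here) and the percent significant at adjusted p < 0.05.

**Shapley attributions** are interventional: a coalition's value is the
mean model output over background rows with coalition features replaced by
the explained row's values; exact subset enumeration up to 10 features
(local accuracy to numerical precision), permutation sampling beyond.
The additive closed form, symmetry and dummy axioms, and exact-vs-sampled
agreement are tested.

**Confound checks** mirror the published battery: within-group Spearman
correlations of age against the top-10 discriminative features
(BH-corrected), an age-augmented logistic model (M2) against the
features-only model (M1) compared by held-out accuracy with McNemar's
paired test and maximum coefficient change, within-group sex Mann-Whitney
tests, a chi-square audit of the error indicator against age group and
sex, and a screening flag for demographic features with mean |attribution|
below 0.01.

# Problem sizes and runtime

The default experiment consumes generator feature *tables* directly;
synthesizing and extracting 4 × 60 s audio for a full cohort is
deliberately not part of the default pipeline (the extraction stage is
exercised by its own parameter-recovery suites on short phonation
signals). Default sizes, chosen for single-CPU practicality and stated
here as the package's own: cohort 172 participants; 72 features per task
(62 signed + 10 noise); repeated 5-fold CV; search budget 8; bootstrap
1000. The test suite uses smaller cohorts (6–40 per group), 1–3 repeats
and budgets 1–2; the acceptance script uses the full cohort with budget 6
and 3 repeats. Parameter-recovery simulations use 1.2–1.5 s phonation at
16 kHz over 50 seeds.

# What passing tests do and do not show

The generator emulates group structure, signed mean shifts with Gaussian
noise, block collinearity, imbalance, and discordance flags. It does not
emulate: non-Gaussian feature distributions, task-correlated noise,
recording-condition variability, longitudinal drift, transcription errors
in the alignment, or any linguistic content (the span task's sentence
materials are out of scope — only timing/acoustic structure is modelled).
Passing the end-to-end criteria therefore shows the *pipeline machinery*
is correct and leakage-free at realistic sizes and effect magnitudes —
not that comparable AUCs would be reached on clinical recordings, whose
headline numbers are not reproducible without the private cohort.

Other known limitations: jitter→shimmer cross-talk in the phonatory
front-end (above); LPC bandwidths are kernel-inflated (monotone, not
calibrated); the hierarchical branch folds shrink when a branch class is
small; and the Bayesian test's `rho` is an approximation whose exact
published counterpart is unstated.
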