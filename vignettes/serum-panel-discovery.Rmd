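---
title: "Serum metabolomics panel discovery: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum metabolomics panel discovery: models, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocmetab)
```

`ocmetab` implements an untargeted LC-MS serum biomarker-discovery workflow
for a two-class case/control design: curation of a run-level peak-area
table, linear-SVM classification with a "metabolic score" decision
function, nested leave-one-out recursive feature elimination (SVM-RFE) for
minimal panel selection, oPLS-DA validation with permutation testing,
univariate feature summaries, and the adduct/monoisotopic-mass arithmetic
used to annotate discriminant features. Because real cohort data are not
redistributable, the package ships a synthetic-data generator that emulates
the study design end to end; every downstream stage is exercised and tested
against it.

This vignette records the scientific content of each stage: the model, its
assumptions, the tunable parameters and their defaults, the numerical
choices, and — importantly — what the procedures can and cannot be expected
to do. Several properties one might naively expect of this workflow are
*not* true (and our tests assert what is true instead); those are discussed
in their sections.

## The emulated study design

The generator (`synthetic_config()`, `simulate_run_table()`) produces a
run-level table shaped like the output of peak-detection software: one row
per injection with acquisition metadata, one column per feature (a
retention-time/m/z pair in real data), entries are peak areas with absent
peaks recorded as missing.

Design defaults emulate a serum profiling study of 46 early-stage cancer
(class C) and 49 age-matched control (class N) samples:

* every sample injected in **duplicate**, with a seeded shuffle constrained
  so the two injections of a sample are never consecutive;
* samples split into **8 class-balanced batches** run contiguously;
* a **pooled QC** injection (the average composition of all study samples,
  mirroring a physically pooled aliquot) before every 8th study run;
* **11 blank runs** (a sample blank plus mobile-phase blanks) spread across
  the sequence. A blank contains no serum metabolites: only a small
  background/solvent feature set (`blank_detect_rate`, default 8% of
  features, drawn outside the planted panel) is detected in blanks, at
  `blank_baseline` (1%) of the median study area;
* with the defaults this yields about 225 collected runs; the total is
  emergent from the design rather than forced.

Peak areas are **lognormal**: feature `j` has base log-area
`mu_j ~ N(10, 1.5^2)` and biological between-sample SD
`log_area_sigma = 0.5` on the natural-log scale — the standard
positive-skew model for integrated peak areas, giving a realistic four-
orders-of-magnitude dynamic range. On top of the biological signal each
injection gets technical noise (`replicate_cv = 0.12`, a conventional
10–15% replicate CV for UPLC-MS; the source study reports no replicate CV,
so this is a field convention, not a reproduced value), a per-injection
total-intensity multiplier (`tic_scale_sigma = 0.2`), a per-(batch,
feature) multiplicative shift (`batch_effect_sigma = 0.1`), and — on a 5%
subset of features — a monotone acquisition-order drift
(`drift_slope = 0.004` per run, i.e. roughly 2.5-fold over a full
sequence, the kind of trend a pooled QC series is meant to expose).
Detection-limit censoring removes peaks with probability logistic in their
log-area, calibrated so about `missing_rate = 5%` of study/QC entries are
missing, concentrated in low-abundance features — which gives the presence
filter realistic targets.

A **planted panel** of 16 features (drawn from the abundant half, so they
survive censoring) carries standardized log-scale class effects drawn from
U(1.5, 2.5) with mixed signs; the generator returns the ground truth
(planted ids, effects, drift ids, background ids) so recovery is testable.
What the generator does *not* emulate: retention-time structure, isotope
patterns, correlated metabolite modules, non-monotone drift, and
cohort-level heterogeneity (age, site, comorbidity effects on the
metabolome). Passing recovery tests on this generator therefore shows the
machinery is correct, not that real cohorts behave this way.

## Curation

`curate()` composes, in order: presence filter → total-area normalization →
QC drift filter → blank-baseline filter → duplicate averaging. The order
follows the narrative of the emulated workflow (exported areas are
normalized before feature vetting); `normalize_first = FALSE` reorders for
sensitivity analysis. Every stage is also exported on its own, and the
`CurationReport` records exactly which feature fell at which stage.

* **Presence filter** — a feature must be detected (non-missing, area > 0)
  in at least `min_runs = 40` of the collected runs.
* **TIC normalization** — each run's areas are divided by that run's total
  peak area; afterwards every run sums to 1. Note the compositional
  consequence: shares are coupled across features (see the RFE section).
* **QC drift filter** — per feature, an OLS regression of pooled-QC area on
  acquisition order (`run_index`; acquisition time selectable). The rule
  "slope more than one standard deviation from zero" is read as
  `|slope| > SE(slope)`, the standard error of the OLS slope estimator —
  the dimensionally coherent reading; `rule = "span_sd"` implements the
  alternative reading `|slope| x span > SD(QC areas)`. **Operating
  characteristics**: `|slope| > SE` is a t-test at threshold 1, so for a
  drift-free feature the removal probability is `P(|t| > 1) ~ 1/3` (higher
  when batch effects autocorrelate the QC series). This is intrinsic to the
  rule, not an implementation artifact: the filter is *harsh on clean
  features by construction*, which is consistent with workflows that cut
  feature lists from thousands to hundreds. Strong drifters (total drift
  several times the QC noise) are removed essentially always; our tests
  assert exactly these two facts rather than a false "keeps all clean
  features" ideal.
* **Baseline filter** — the baseline is the maximum blank-run area, per
  feature by default (`per_feature = FALSE` gives one global scalar; the
  source wording supports either). A feature is kept if, in at least one of
  the groups {all study samples, class C, class N}, at least
  `fraction = 0.5` of samples sit at or above `multiple = 10` times the
  baseline. On normalized data this purges blank-background features
  aggressively: a blank's detected shares sum to 1, so any feature
  detected in blanks has a blank share far above typical study shares.
* **Duplicate averaging** — replicate areas are averaged per sample; a peak
  absent in a replicate contributes 0 (absent in both replicates averages
  to 0); gap filling is out of scope. QC and blank runs are excluded from
  the resulting samples-by-features matrix.

All filters are idempotent (decisions are per-feature and do not depend on
which other features survive), which the suite checks.

## The linear SVM and the metabolic score

Classes are coded `N -> -1`, `C -> +1`. The classifier is a linear
soft-margin C-SVC: the hyperplane `w x' + b = 0` maximizing the margin
subject to `c_i (w x_i' + b) >= 1 - xi_i` with penalty `C sum xi_i`. The
decision value `w x' + b` on the autoscaled sample vector is the
**metabolic score**: positive predicts cancer, negative control. A score of
exactly 0 is classified N with a warning — the conservative call for a
screening context; only the strict signs are defined by the convention.

Features are **autoscaled** (mean 0, unit sample SD) before fitting; the
scaling is stored in the model so raw-scale samples can be scored. The
regularization constant is unstated in the emulated workflow; the default
is `cost = 1`, exposed everywhere, and results should be read as
conditional on it.

The solver is an in-package SMO dual solver (Rcpp) for the linear kernel
with maximal-violating-pair working-set selection and an **unpenalized
bias** (the standard SVM convention). A compiled solver is used because the
nested-LOOCV RFE below needs on the order of 10^4–10^5 fits per run; fold
fits reuse one Gram matrix per panel. Convergence tolerance is `1e-6` for
single fits and `1e-4` inside cross-validation loops (decision signs are
insensitive to the looser tolerance); the iteration cap is 2x10^5 with a
warning on hitting it. The suite cross-checks the solver against analytic
max-margin solutions and against an independent libsvm implementation
(`e1071`) to 1e-4 on random soft-margin problems.

## Nested-LOOCV recursive feature elimination

At panel size J the procedure runs full leave-one-out cross-validation
(n models on n-1 samples), averages each feature's signed weight across the
n fold models, records accuracy/sensitivity/specificity on the held-out
scores, and eliminates the feature with the smallest `|average weight|`
(ties broken by the earliest-indexed feature, so reruns are identical).
This repeats down to one feature; `select_optimal_panel()` then returns the
smallest panel among those achieving the lexicographic maximum of
(accuracy, sensitivity, specificity) — the "minimum of N features"
semantics. Averaging the signed weights and then taking the absolute value
is the default importance; fold-averaged `|w|` is available via
`importance = "mean_abs"`.

Two scaling modes exist: `"global"` (default) autoscales once before
elimination begins, reproducing workflows that preprocess "prior to
SVM-RFE"; `"fold"` rescales inside every training fold. The global mode
leaks one held-out sample into each fold's scaling; at these sample sizes
the measured effect on accuracy is below noise in either direction, so the
modes are documented as equivalent in practice rather than ordered.

**What this procedure's metrics mean.** The per-step "LOOCV" metrics are
honest for a *fixed* feature set, but the elimination decisions reuse all
samples (each fold's weights see every sample except its own holdout), so
the feature sets at small panel sizes are themselves tuned to the full
cohort. This is the well-known selection bias of non-nested wrapper
selection: on label-permuted data the procedure still finds small panels
with near-perfect per-step "LOOCV" accuracy. Two consequences, both
verified on the generator and reflected in the tests:

* the minimal panel reaching 100% is typically far *smaller* than the
  planted panel (a handful of strong features, cherry-picked with
  full-cohort information, already separates 95 samples), so the selected
  panel size is not an estimate of the true panel size;
* because TIC normalization makes shares compositional, planted features
  are partly redundant, and elimination freely trades one planted feature
  for another. The robust recovery statements are that late elimination
  steps are dominated by planted features and the selected panel is almost
  always a planted *subset*.

Plain `loocv_evaluate()` on a fixed feature set has none of this bias; on
random labels its accuracy centres near 50% (slightly below, the usual
LOOCV pessimism for balanced noise), which the suite checks over 200
simulations.

## oPLS-DA validation

`fit_oplsda()` autoscales the matrix, codes the class -1/+1, and fits one
predictive component plus `n_ortho` orthogonal components in the
orthogonal-signal-correction style: the predictive weight is
`w = X'y / ||X'y||`; each orthogonal component removes from X the part of
the current loading orthogonal to `w`. Because deflation never touches the
covariance with y, orthogonal scores carry exactly zero class covariance,
and with `n_ortho = 0` the model is one-component PLS-DA; both facts are
tested to 1e-8. Adding orthogonal components can only sharpen the
predictive component, so fitted R²Y is non-decreasing in `n_ortho`. When
`n_ortho` is unspecified it is chosen by maximizing leave-one-out Q²
over 0–3 components (binary y rarely supports more).

`oplsda_cv()` computes `Q² = 1 - PRESS/TSS` on held-out class codes under
four split schemes: leave-one-out; venetian blinds (cyclic assignment by
sample index, 10 splits); contiguous blocks (index ranges, 10 splits); and
random subsets (10 splits, 10 seeded iterations, Q² averaged). Fold models
are refit from scratch including their autoscaling, so Q² is leakage-free.
`permutation_test()` randomizes the class labels and reports the add-one
empirical p-value `(1 + #{Q²_perm >= Q²_obs}) / (n_perm + 1)`. Null Q² is
non-positive in the median (predicting from noise is worse than predicting
the mean), which the suite verifies over 200 simulations.

## Univariate summaries and bias inspection

Per feature, `feature_summaries()` reports class means of the averaged
normalized areas, the **signed fold change** (`+mean_C/mean_N` when C is
higher, `-mean_N/mean_C` otherwise; magnitude always >= 1, +1 at equality —
the only reading consistent with "positive = elevated in cancer"), the
Mann-Whitney U (reported as `min(U_C, U_N)`) with a two-sided p (exact for
<= 8 untied observations per group, normal approximation with tie
correction otherwise, via the stats machinery), and a significance tier
(p < 0.05, p < 0.10, ns — no multiplicity correction, matching the
emulated analysis). Fold changes are undefined (NA) when a class mean is 0.

`pca_bias_check()` autoscales, runs PCA, and supplements the usual PC1/PC2
visual check for batch, collection-day or site clustering with an F-like
ratio of between-group to within-group mean squares on the PC1/PC2 scores;
separated clusters push it far above 1 while shuffled labels keep it in the
permutation envelope.

## Mass annotation

`monoisotopic_mass()` sums fixed most-abundant-isotope masses (C 12 exact,
H 1.00782503, N 14.00307401, O 15.99491462, P 30.97376200, S 31.97207117,
Na 22.98976928 — embedded constants, no lookups). `ion_mz()` computes
`(M + gains - losses ± z·m_e) / z` with named negative-mode presets. Two
conventions deserve note:

* **Electron mass is ignored by default** (the "H-atom convention"):
  reference annotation tables in this field print `[M-H]⁻` values equal to
  `M - mass(H atom)`, about 0.5 mDa away from the electron-corrected
  physical value. `electron_correction = TRUE` enables the exact
  convention.
* The preset labelled `"[M-CHO-H]-"` encodes the loss of CH₂O plus a
  proton (total CH₃O): the literal `M - CHO - H` arithmetic does not
  reproduce the reference m/z printed under that label, while the CH₂O
  reading does; the discrepancy is documented on the preset.
* `"[M-H]2-"` is interpreted as the doubly deprotonated `[M-2H]²⁻` (the
  printed values are consistent with `(M - 2H)/2`).

`formula_candidates()` enumerates compositions within per-element bounds
under a mass tolerance (default workflow value: 10 mDa), sorted by absolute
error, with optional nitrogen-rule and RDBE >= 0 filters; it refuses bound
boxes above 10^7 combinations. `annotate_masses()` reports theoretical m/z
rounded to 4 decimals and derives ppm/mDa errors from the rounded value,
because printed annotation tables state m/z at that precision and their
error columns are consistent with the printed values (`mz_digits = NULL`
disables this). `screening_ppv()` is the Bayes PPV
`sens·prev / (sens·prev + (1-spec)(1-prev))` used to reason about
population screening feasibility for a low-prevalence disease.

## Pipeline

`run_pipeline()` chains simulate → curate → SVM-RFE → oPLS-DA validation →
summaries (→ annotation when a table of observed ions is supplied), writes
every intermediate (run table, ground truth, sample matrix, curation
report, RFE trace, model, per-sample score-vs-age table, validation JSON,
summaries) under one output directory, and returns a manifest with a config
hash and per-file checksums. One global seed drives the generator and all
CV/permutation randomness, so a run is a pure function of its
configuration; re-running an identical config reproduces identical
checksums for all deterministic outputs.

## Problem sizes used by the tests

The full study profile (95 samples x 255 features, complete RFE) appears in
the acceptance checks, where 20 seeds take a few minutes in total thanks to
the compiled solver. Unit and property tests use scaled-down profiles
(10–30 samples, 10–40 features, 60–200 Monte-Carlo replicates) chosen so
each statistical property has clear resolution while the whole suite stays
fast; oracle comparisons (fold enumeration, OLS closed forms, Mann-Whitney
enumeration, libsvm agreement) use n <= 12 where exhaustive computation is
exact.

## Known limitations

* The generator's independence assumptions (features, samples) understate
  the correlation structure of real serum metabolomes; recovery results on
  synthetic data are a correctness check, not a clinical claim.
* The QC drift rule at one standard error is intentionally literal; users
  who want a specificity-controlled screen should raise the threshold or
  pre-filter by presence first (the rule's null behavior is documented
  above and characterized in the tests).
* RFE panel sizes inherit wrapper-selection bias (discussed above);
  unbiased panel-size estimation would require an outer validation loop,
  which the emulated workflow does not define.
* No retention-time modelling, isotope scoring, or MS/MS evidence is
  implemented; annotation is mass arithmetic only.
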