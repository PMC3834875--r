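---
title: "Evaluating staging prediction models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating staging prediction models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageval)
```

## The scientific setting

Pre-operative staging of prostate cancer asks a binary question: is the
tumour organ-confined (OC), or has it escaped the gland (non-organ-confined,
NOC — extracapsular extension, seminal vesicle invasion, or lymph node
involvement)? Routine clinical variables — serum PSA, clinical stage from
digital rectal exam, and the biopsy Gleason score — carry limited
information about this, and the point of this package is a disciplined way
to *measure* how limited: discrimination, calibration and decision-curve
analysis applied to cross-validated predictions, with a lookup-table
comparator of the Partin type.

## The synthetic cohort generator

Real surgical series with linked pre-operative and pathological data are
rarely depositable, so `sample_cohort()` emulates one. The generative model
draws, per patient:

1. **Pathological stage first**: NOC with probability `noc_prevalence`
   (default 0.30), then ECE/SVI/LNI within NOC with `noc_split` (default
   0.63/0.27/0.10). The binary NOC label is derived, never stored
   independently, so label and stage cannot disagree.
2. **PSA** from a stage-conditional log-normal. Published series report
   means and medians, not distributions; right-skew with mean > median makes
   the log-normal the natural choice, and its two parameters are *solved*
   from the (mean, median) pair: `meanlog = log(median)`,
   `sdlog² = 2·log(mean/median)`. Defaults: OC mean 7.6 / median 6.7, NOC
   mean 8.6 / median 7.5 ng/ml. Values are clamped to `psa_clip`
   (0.7–40 ng/ml), the plausible assay range; with the default parameters
   the clamp affects well under 0.1% of draws, so the stated moments are
   preserved. The implied overall mean is 0.7·7.6 + 0.3·8.6 ≈ 7.90 ng/ml.
3. **Age** truncated-normal on `age_range` (40–80 y), means 60.7 (OC) /
   62.2 (NOC), common SD 7.5 y (back-solved from a typical cohort CI),
   rounded to whole years. Truncation is by inverse-CDF, not rejection, so
   draws are exact and O(n).
4. **Biopsy Gleason score** from stage-conditional six-category
   distributions; **clinical stage** and **family history** independent of
   stage (their group comparisons are null in the series this emulates).
   "Not reported" clinical stage is a legitimate sampled level, not
   missingness: such patients were retained in the original analyses and
   must flow through modelling.
5. **Prostatectomy Gleason score** via per-category (decrease, no change,
   increase) triples. Concordance tables report the *direction* of change
   at the five-group reporting scale (≤6, 3+4, 4+3, 8, 9–10), so a move is
   defined as one *group* up or down, clamped at the ends; an unchanged
   score keeps its exact six-level category, and a moved score takes a
   representative category of the target group. This makes the grouped
   tabulation recover the configured triples exactly — defining moves on
   the six-level scale instead would silently convert moves within the ≤6
   group into apparent concordance.

What the generator does **not** emulate: correlation between PSA and
Gleason score within a stage group (covariates are conditionally
independent given stage), inter-hospital grading variation, and any
within-T2 substructure. Consequently the synthetic cohorts are mildly
*easier* to model than real data in some directions and harder in others;
passing tests show the pipeline measures what it claims to measure, not
that any specific AUC is attainable in a real series.

All randomness flows from one master seed through `derived_seed(master,
stream)` — a small polynomial hash onto 32-bit seed space — so the
generator, fold assignment and each model's internal randomness have
independent, reproducible streams.

## Descriptive statistics

`summarize_cohort()` mirrors the standard cohort-characteristics table.
Choices the published conventions leave open:

- *t-test vs Mann-Whitney*: selected by a Shapiro-Wilk check per group at
  α = 0.05 (configurable). Shapiro-Wilk caps n at 5000, so larger groups
  are checked on a fixed-seed subsample.
- *Chi-square* without continuity correction on the full contingency
  table; expected counts below 5 are flagged in a note, not escalated to an
  exact test.
- Reported percentages round half away from zero to one decimal, matching
  the usual table style (base `round()` rounds half to even, which can
  differ in the last digit).

## Cross-validated modelling

`assign_folds()` partitions uniformly at random into k = 5 folds whose
sizes differ by at most one. Each model is trained on four folds and
predicts the fifth; pooled out-of-fold probabilities give one prediction
per patient from a model that never saw that patient. Metrics are computed
on the pooled set (one number per model) rather than averaged per fold —
this matches how a single summary value per model is usually reported, and
is less noisy at n in the hundreds.

Feature encoding is fixed and documented: PSA continuous and
untransformed (no transform is standard in this literature's lookup-table
lineage); clinical stage reference-coded against T1c with NOT_REPORTED as
its own level; biopsy Gleason reference-coded against ≤5 in category
order — 8 columns in total.

Hyperparameters have no published reference here, so defaults are ordinary
field practice, all configurable: logistic regression unpenalized; random
forest 500 trees with default feature subsampling; kNN with k = 25
neighbours on training-standardized features, predicted probability equal
to the neighbourhood NOC fraction. Univariate models are single-covariate
logistic fits — the simplest probability-producing choice for evaluating a
clinical variable in isolation.

## Discrimination

Seven metrics at a threshold: sensitivity, specificity, Youden index
J = Se + Sp − 1, PPV, NPV (undefined ratios returned as flagged `NA`),
plus the threshold-free Brier score and AUC. The AUC is the Mann-Whitney
pair probability computed via midranks (ties count ½), which equals the
trapezoidal area under the empirical ROC; tests verify it against
exhaustive pair enumeration and an independent ROC implementation.

No single classification threshold is canonical for this problem, so the
default rule maximizes the Youden index over the observed probabilities
(smallest threshold on ties, ties at the cut classified positive); fixed
and prevalence rules are available. The Youden rule is the one a staging
study with no stated preference between sensitivity and specificity
implies.

## Calibration

`loess_calibration()` regresses the binary outcome on the predicted
probability with local quadratic fitting and tricube weights (span 0.75,
degree 2 — ordinary smoother defaults, configurable), evaluated on a
101-point grid over the *observed* prediction range (not [0, 1]: a model
whose predictions live in a narrow band should be displayed there) and
clamped to [0, 1]. Models with fewer than 10 distinct predicted values —
e.g. one driven by a 3-level factor — cannot support a local fit; the
curve is omitted with a diagnostic rather than extrapolated. Error bars
come from quantile bins (default 10) with Wilson 95% intervals, which
behave correctly near 0 and 1 where Wald intervals fail; empty bins (tied
quantiles) are merged with neighbours.

## Decision curve analysis

Net benefit at threshold probability Pt is
NB = TP/n − (FP/n)·Pt/(1 − Pt), with classification at the cut Pt itself —
the standard convention that makes Pt simultaneously the classification
threshold and the harm weight. The default grid runs 1–50% in 0.5% steps:
above 50% a clinician would be treating NOC as more likely than not, which
is outside this decision's plausible range. Treat-all and treat-none are
computed alongside every model; algebraically, treat-all crosses zero
exactly at the prevalence, and the tests assert both this identity and the
sensitivity/specificity reformulation of net benefit as two independent
routes to one value.

## Partin-style lookup tables

`load_partin_table()` enforces the structural invariants a published table
satisfies: PSA bands tile (0, ∞) half-open upper-inclusive, each cell's
four stage probabilities sum to 100 within ±3 points (published cells are
rounded). The published 2007 probability values are third-party data and
are not shipped; the bundled table is synthetic (named so) and exists for
tests and examples. Evaluation is stratified by clinical stage, since each
printed sub-table conditions on stage; patients with stage NOT_REPORTED
are excluded and counted — how to push them through a stage-specific table
is genuinely undefined. The outcome label defaults to outcome-vs-rest
(e.g. ECE vs not-ECE), with NOC-vs-OC labelling available, because a
table's ECE prediction and a model's NOC prediction answer subtly
different questions and both comparisons are legitimate.

## Problem sizes and test design

The test suite exercises the generator at n = 10,000 (moment recovery
within 3 standard errors), calibration oracles at n = 5,000 (self-
calibrated simulation within 0.05 of the diagonal), exhaustive AUC
enumeration at n ≤ 50, and full pipelines at n = 150–600 — sizes chosen so
the whole suite runs in well under a minute while every stochastic
assertion retains comfortable power. Stochastic tests fix their seeds;
none was selected by its outcome.

## Known limitations

- Conditional independence of covariates given stage caps the achievable
  multivariable AUC near the best single predictor's; this mirrors the
  weak-signal regime the framework targets but is still a simplification.
- The Gleason transition moves at most one reporting group per patient;
  real upgrades occasionally jump two.
- Calibration reproduction is qualitative by design: smoother settings
  behind any specific published figure are unknowable.
- No confidence intervals on AUC or net benefit; the framework reports
  point estimates, as its reference analyses do.
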