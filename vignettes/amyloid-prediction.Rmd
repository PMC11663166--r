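---
title: "Predicting CSF amyloid status from memory-clinic data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CSF amyloid status from memory-clinic data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloidscreen)
```

## The problem

Cerebrospinal-fluid (CSF) analysis is the reference standard for
establishing brain amyloid pathology in the diagnostic work-up of
cognitive impairment, but lumbar puncture is invasive and
resource-intensive. Memory clinics therefore need screening tools built
from routinely available data — structural MRI, neuropsychological
testing, APOE genotype — that stratify patients by their probability of
amyloid positivity before more advanced confirmation (CSF or amyloid
PET), and that flag who would plausibly be eligible for anti-amyloid
monoclonal antibody treatment.

`amyloidscreen` implements that screening pipeline end to end:

1. **Data-driven CSF cutoffs.** The CSF A&beta;42/A&beta;40 ratio
   (carried throughout on the &times;10 scale) is bimodal: an
   amyloid-pathology component at low ratios and a normal component at
   high ratios. A two-component Gaussian mixture is fitted per assay
   platform and the amyloid-positivity cutoff is the point where the
   weighted component densities cross. Positivity is a ratio *strictly
   below* the cutoff; the reference cutoffs are 0.60 (Innotest ELISA)
   and 0.86 (Lumipulse), kept assay-specific and never pooled because
   the two platforms are not harmonized.
2. **Youden-optimal dichotomization.** Each continuous marker is turned
   into a one-point rule at the cutoff maximizing the Youden index
   $J = \mathrm{sens} + \mathrm{spec} - 1$.
3. **Composite point scores.** A two-region volumetric score (0&ndash;2:
   hippocampal volume &lt; 6.94&nbsp;ml, angular gyrus volume &lt;
   7.80&nbsp;ml, normalized volumes) and a four-item score (0&ndash;4)
   adding RAVLT immediate recall &lt; 42 points and APOE4 carriage.
4. **Diagnostic-accuracy evaluation.** Per-threshold sensitivity,
   specificity, and prevalence-adjusted predictive values; the score's
   AUC (Mann&ndash;Whitney on the ordinal score) with DeLong confidence
   intervals; paired DeLong tests between correlated markers.
5. **Eligibility screening.** A rule engine for the five appropriate-use
   criteria for anti-amyloid antibodies, and evaluation of the scores as
   predictors of eligibility.

A seeded synthetic-cohort generator reproduces the group-level
structure of a real-world memory-clinic population (290 patients, 92
amyloid-positive), so that every stage is exercisable and testable
without any patient-level data, which are not publicly deposited.

## Statistical machinery

### Gaussian mixture cutoffs

`fit_csf_gmm()` maximizes the $k$-component Gaussian mixture likelihood
by expectation-maximization. Numerical choices:

* log-space responsibilities (log-sum-exp) for stability;
* convergence when successive log-likelihoods differ by `tol = 1e-8`,
  capped at `max_iter = 500`; the trace is retained and is
  non-decreasing by the EM guarantee (asserted in the tests);
* `n_restarts = 5`: the first restart initializes component means at
  evenly spaced sample quantiles (deterministic) or by k-means; later
  restarts draw random quantile positions, and the best run by
  log-likelihood wins;
* component SDs are floored at $\sqrt{10^{-6}\,\widehat{\sigma}^2}$ of
  the sample variance, guarding against variance collapse onto a single
  point;
* fewer than $2k$ distinct values, or an all-constant sample, is
  refused with a diagnostic rather than fitted.

`derive_cutoff()` defines the cutoff as the weighted-density crossing
between the two component means — equivalently the posterior-0.5 point,
the standard mixture-based dichotomization — located by bisection to
1e-8. When the densities do not cross between the means (possible with
very unequal weights and variances) the crossing nearest the lower mean
is returned, computed from the closed-form density-equality quadratic,
and flagged via the `between_means` attribute; a mixture whose weighted
densities never cross is refused.

### ROC toolkit

The empirical ROC (`empirical_roc()`) collapses ties into single
vertices (diagonal segments); `trapezoid_auc()` then equals the
Mann&ndash;Whitney estimator
$P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)$ exactly, which the tests verify
against an $O(n^2)$ pairwise oracle. `auc_from_operating_points()`
rebuilds a discrete score's ROC polygon from per-threshold
(sensitivity, specificity) rows in percent — exactly the arithmetic
needed to recompute a published threshold table's AUC.

`youden_cutoff()` searches candidate cutoffs at midpoints between
consecutive distinct values plus the two all-or-none extremes. Ties in
$J$ break toward the cutoff classifying fewest records as positive
(the most specific rule), deterministically. Because candidates are
data midpoints, the induced classification is invariant under strictly
monotone marker transforms.

DeLong variance and covariance use midrank placement values
($O(n \log n)$), a Wald CI on the AUC scale truncated to $[0,1]$
(logit-scale variant behind `ci_method = "logit"`), and a two-sided
normal reference for the paired AUC difference. Degenerate perfect
separation yields SE 0 and a point CI rather than an error.

Composite-score AUCs are computed directly on the ordinal score. An
evaluation routed through a single-predictor binomial logistic
regression would give the identical ROC, because the fitted
probabilities are a monotone transform of the lone predictor; the
direct Mann&ndash;Whitney route avoids a needless model fit.

Predictive values come from Bayes' rule at an explicit prevalence:
analyses on different complete-case subsets use each subset's own
prevalence. Percentages are carried at full precision internally and
rounded only at report time (one decimal for sensitivity, specificity,
PPV, NPV; two to three for AUCs).

### Composite scores and missing data

Item rules are strict inequalities: a hippocampal volume exactly at
6.94 ml scores zero. A record missing any item value gets a missing
score and is dropped from that evaluation (complete-case per analysis),
and the evaluation's PPV/NPV use the analysed subset's own prevalence.
This policy was chosen because the per-variable observed counts differ
by variable, which implies each published analysis ran on its own
complete-case subset. Cutoffs default to the frozen published values
for reproducibility; `cutoff_mode = "youden"` (or
`refit_score_cutoffs()`) re-derives them on the input cohort instead.

Region selection (`select_regions()`) averages left/right volume
variants per record before computing candidate AUCs, picks the best
candidate from the medial-temporal and cortical groups, and breaks ties
alphabetically. The candidate lists are arguments, since no exhaustive
candidate inventory is fixed by the method.

### Eligibility rules

`assess_eligibility()` returns, for every record, an eligible flag plus
machine-readable failure reasons (`"diagnosis"`, `"cognition"`,
`"mri"`, `"anticoagulant"`, `"amyloid"`, `"etiology"`, or
`"missing:<field>"` when an enabled criterion cannot be checked).
Two interpretation points were genuinely open and are resolved as
explicit, configurable defaults:

* **MMSE vs MoCA.** The cognitive criterion reads "MMSE 21&ndash;30 (or
  MoCA 17&ndash;30)"; the "or" is read as a fallback, so when both are
  present the MMSE governs. `moca_fallback_only = FALSE` switches to
  either-test-in-range.
* **Non-AD etiologies.** "No evidence of non-AD neurologic disorder" is
  operationalized as a configurable disallow-list of etiology tags
  (default: FTD, vascular, alcohol, psychiatric) applied on top of the
  diagnosis check; missing tags do not exclude.

Imaging contraindications (microbleeds/ARIA risk) are deliberately not
modelled: complete MRI reports are typically unavailable in this
setting, and none of the modelled criteria stand in for them.
Relaxing any single criterion can only grow the eligible set, a
monotonicity property the tests assert.

## The synthetic cohort generator

`cohort_config()` encodes the printed group-level structure: fixed
group sizes 198 amyloid-negative / 92 amyloid-positive (fixed, not
binomially sampled, so the 92/290 prevalence is exact by construction),
per-group Gaussian means/SDs for volumes, cognitive scores and atrophy
rating scales, per-group APOE4 carrier rates (29.8% / 69.6%), diagnosis
mixes (67.1/19.1/13.6% vs 22.8/25.0/52.1% SCI/MCI/dementia), and
per-variable observed counts for missingness (e.g. RAVLT observed in
254 of 290).

Choices a user should be aware of:

* **Conditional independence.** Only per-group marginals are published,
  so markers are drawn independently given amyloid group. Real data
  correlate (atrophy with memory scores, age with everything); the
  synthetic four-item score AUC is therefore an *independence-case*
  figure. The tests check that its seed-to-seed distribution covers the
  published 0.82; they cannot show the score attains 0.82 on correlated
  real data.
* **Clipping and rounding.** Continuous draws are clipped into valid
  ranges (MoCA/MMSE into [0, 30], rating scales into their 0&ndash;3 or
  0&ndash;4 ranges) and integer scales rounded; computed rating scales
  stay continuous ("even decimal results") at full precision, since no
  fixed reporting precision is published for them. Clipping bounds live
  in the config, so the unclipped Gaussian case remains testable.
* **CSF ratio mixture.** Per assay, a record's ratio is drawn from the
  mixture component matching its group, rejection-sampled onto the
  correct side of the assay cutoff, so labels and ratios never
  contradict. Component parameters are not published; the defaults
  (Innotest: positive N(0.44, 0.075&sup2;), negative N(0.96, 0.16&sup2;);
  Lumipulse: N(0.65, 0.10&sup2;), N(1.28, 0.20&sup2;); weights
  0.317/0.683 matching the prevalence) were fixed once so that each
  assay's true density crossing sits near its reference cutoff
  (&asymp;0.606 and &asymp;0.858).
* **Assay mix.** The Innotest&rarr;Lumipulse platform switch happened
  mid-recruitment; 45% of records are assigned Innotest, approximating
  the time split. No cross-assay harmonization is modelled.
* **Unpublished rates.** MRI availability defaults to 1.0 (the whole
  cohort underwent MRI) and anticoagulant use to 8%/10% per group, a
  realistic figure for a memory clinic with mean age around 60. The
  generator's eligible fraction is consequently its own implied joint
  rate, not the published eligible count of 45; published-table
  eligibility arithmetic always uses 45/290 explicitly.
* **Missingness** is completely at random (the mechanism behind the
  published per-variable Ns is uncharacterized), scaled proportionally
  for non-default cohort sizes, and never touches `id` or the amyloid
  label. Under MCAR the complete-case evaluations are unbiased; with
  informative missingness they would not be.

Identical `(config, seed)` pairs yield byte-identical tables, and all
pipeline randomness flows from one root seed split deterministically
per stage.

## What the checks do and do not establish

The test suite verifies, among other things: exact agreement of the
trapezoidal AUC with the Mann&ndash;Whitney oracle and of the Youden
search with exhaustive enumeration; DeLong SE/CI agreement with an
independent implementation (pROC) and with a 2,000-replicate bootstrap
at cohort scale (n = 290); near-nominal CI coverage and paired-test
type-I error in simulation; EM agreement with an independent mixture
implementation (mclust); recovery of configured generator marginals
within CLT bounds; and the published-table arithmetic (threshold tables
integrating to the published AUCs, Bayes' rule reproducing the
published predictive values at prevalences 92/290 and 45/290).

Problem sizes used by the checks: 100 simulated cohorts of n = 290 for
the end-to-end score distribution; 50 mixture fits at n = 290 for
cutoff recovery; 1,000 replicates at n = 500 + 500 for CI coverage;
2,000 replicates at n = 145 for paired-test type-I error.

Two published quantities are deliberately **not** asserted anywhere:

* the hippocampal AUC of 0.68 — its binormal approximation from the
  printed group moments is about 0.66, a reminder that real volumetric
  data are not exactly Gaussian (the angular gyrus, RAVLT and APOE4
  analytic cross-checks do land within &plusmn;0.01 of their published
  values);
* the between-marker paired DeLong p-values of the real cohort
  (0.048, 0.050) — these depend on patient-level correlations that no
  marginal-based simulation can reproduce. The machinery that would
  compute them is instead validated by calibration simulations and
  cross-implementation agreement.

One further printed inconsistency is carried, not resolved: the
published text reports a 68.9% sensitivity for the volumetric score at
threshold &ge;1 where the published table prints 86.9%; the table value
is arithmetically consistent with the published AUC of 0.722 and is the
one used in the reconstruction checks.

## Known limitations

* The generator emulates marginals, not joint structure; transporting
  the synthetic performance figures to real cohorts is an assumption,
  not a result.
* Apparent (resubstitution) performance only — no cross-validation, no
  weighted or regression-coefficient scores, matching the method being
  reproduced.
* No image processing: volumes and computed rating scales enter as
  numbers; the upstream segmentation pipeline is out of scope.
* Later-generation appropriate-use criteria (lecanemab/donanemab),
  ARIA-risk logic and dosing are not modelled.

## Worked example

```{r example, eval = FALSE}
bundle <- run_pipeline(list(seed = 11), quiet = TRUE)
bundle
print(bundle$evaluations$amyloid_four_item)
write_report_bundle(bundle, "report")
```
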