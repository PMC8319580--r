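---
title: "Second-derivative CT texture biomarkers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-derivative CT texture biomarkers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In locally advanced breast cancer (LABC), neoadjuvant chemotherapy (NAC) is
given before surgery, but only a minority of patients reach a complete
pathological response. Response is currently confirmed months later, on the
surgical specimen. The hypothesis behind this package is that tumor
micro-structure, partially visible in routine pre-treatment contrast-enhanced
CT through partial-volume effects, carries predictive information: spatial
heterogeneity statistics of the tumor ROI differ between eventual responders
(R) and non-responders (NR).

`sdtexture` implements that analysis end to end: texture quantification,
feature selection, imbalance-aware ensemble classification under
leave-one-patient-out (LOPO) cross-validation, and recurrence-free survival
analysis of the predicted cohorts.

## Texture model

Each tumor slice is quantized to `Ng = 128` gray levels by equal-width
binning of the ROI intensity range (making all downstream features invariant
to additive intensity shifts). A 3x3 window slides over the ROI with step 1;
in each window a symmetric gray-level co-occurrence matrix (GLCM) is
accumulated at one-pixel offset along 0, 45, 90 and 135 degrees. Eight
Haralick-type statistics — entropy (ENT), contrast (CON), correlation (COR),
maximum probability (MAX), mean (MEA), homogeneity (HOM), standard deviation
(STD) and energy (ENE) — are averaged over the four directions and assigned
to the window center, producing eight *parametric maps* per slice.

Second-derivative texture (SDT) features apply the identical analysis to
each parametric map: the map is re-quantized over its own observed range and
swept again; `ENT_CON`, for example, is the mean contrast of the entropy
map. With 8 first-pass means and 8 x 8 second-pass means this yields 72
features per slice, aggregated over slices by ROI-area weighting.

Conventions that the common GLCM literature leaves open are fixed as
follows:

* **Homogeneity** uses the inverse difference moment `sum p/(1 + (i-j)^2)`;
  **energy** is the angular second moment `sum p^2`; entropy uses `log2`.
* **Correlation of a constant window** is defined as 1 (perfect
  self-correlation); this keeps maps finite.
* **Windows must lie fully inside the ROI** — no padding, no partial
  windows — so tumor texture is never contaminated by background. The
  validity mask is therefore an eroded ROI, and a slice too small for one
  second-pass window is excluded from aggregation.
* **Constant regions quantize to level 1**; any single level would do, one
  is fixed for determinism.
* **Second-pass quantization** re-bins each map linearly to the same
  `Ng = 128` over its own range; GLCMs need discrete input, so some policy
  is mandatory and the range-relative one mirrors the first pass.
* ROI area is measured in mask pixels, proportional to physical area at
  fixed pixel spacing.

The sliding-window engine is compiled (Rcpp) and is verified in the test
suite against a naive per-pixel R oracle built from `compute_glcm()` and
`texture_features()`.

## Feature standardization and selection

Features are standardized by the robust scaler, `(x - median)/IQR`, with
quartiles by linear interpolation. Inter-feature redundancy is summarized by
the squared Pearson correlation of every pair.

Ranking uses minimum-redundancy-maximum-relevance (mRMR, difference form)
under LOPO: within each fold's training rows, features are discretized into
three bins at mean +/- sd, relevance and redundancy are mutual information,
and the greedy ranking is recorded; fold rankings are consolidated position
by position, assigning each rank the not-yet-placed feature most frequent at
that position (ties broken by mean fold rank, then name — a deterministic
rule). The top 8 features are retained.

Subset selection is strictly forward: starting from the top-ranked feature,
the candidate maximizing the subset score is added until the list is
exhausted; the best-scoring prefix wins. The score is the 0.632+ bootstrap
AUC of the same AdaBoost configuration used by the final model, computed on
each LOPO fold's training rows and averaged over folds (scoring once on the
full table is available via `lopo = FALSE`). With apparent AUC `a`, mean
out-of-bag bootstrap AUC `b` (floored at the no-information rate
`gamma = 0.5`), the relative overfitting rate is
`R = (a - b')/(a - gamma)` clamped to [0, 1], the weight
`w = 0.632/(1 - 0.368 R)`, and the estimate `(1 - w) a + w b'`. Inside
selection the estimator uses `B_sel = 50` bootstrap replicates by default —
enough to stabilize the mean out-of-bag AUC at selection time while keeping
the SFS loop tractable; 300 is reserved for the final voting ensemble.

The consolidated ranking and selected subset are computed once on the full
table and reused in every outer LOPO fold, matching the single final
ranking/subset of the analysis this package operationalizes; note this means
feature selection sees the test patient's row, an optimism source users
should be aware of when quoting the outer cross-validated metrics.

## Imbalance handling and the voting ensemble

Each LOPO training set is balanced by plain SMOTE (k = 3 neighbors, convex
interpolation, seed 14) doubling the minority class, paired with `B = 300`
bootstrap samples of the majority class of the same size; each balanced set
trains one AdaBoost classifier (discrete two-class SAMME) with depth-4
CART weak learners, 150 estimators, learning rate 0.1. The stored
`m_neighbors = 5` parameter belongs to the borderline SMOTE variant and is
kept only for configuration fidelity. The held-out patient is removed
*before* SMOTE and bootstrapping; `lopo_evaluate()` records every original
row index that entered any training computation per fold, so the isolation
is auditable, and the test suite audits it.

Prediction is by majority vote: the vote fraction is the share of the B
members predicting R, and a fraction of exactly 0.5 predicts R (the 50%
threshold is inclusive; configurable). The vote fraction doubles as the
continuous score for ROC analysis. Minority/majority are determined per
fold from the training rows rather than assumed.

The weak learner and boosting loop are implemented in C++ because the
selection-plus-evaluation procedure fits on the order of 10^5–10^6 small
trees; the implementation is deterministic (exhaustive Gini split search,
midpoint thresholds, first-best tie-break), so all randomness flows from R
seeds.

## Response grading and survival

The modified-response (MR) grade maps pathology to 1–5: no size reduction
(1), under 30% (2), 30–90% or very low residual cellularity (3), over 90%
(4), no evident tumor (5); grades 1–2 define NR, 3–5 define R. A reduction
of exactly 30% is grade 3, consistent with NR being "less than 30%".
Recurrence-free survival uses the Kaplan–Meier product-limit estimator and
the log-rank test (chi-square, 1 df), via the survival package, for the
true R/NR split and for each model-predicted split. The univariate feature
comparison is Student's pooled-variance t-test (Welch behind a flag).

## The synthetic cohort generator

No patient CT data ship with the package; `generate_cohort()` provides a
statistically analogous stand-in. Per patient it draws `3 + Poisson(mean - 3)`
slices (default mean 10), each with an elliptical ROI whose axes vary
uniformly between 0.13 and 0.30 of the grid side (area variability for the
weighted aggregation), and fills the slice with a stationary Gaussian random
field: white noise smoothed by an isotropic Gaussian kernel whose width is
the class's correlation length (defaults 2.5 px for R, 1.2 px for NR),
rescaled to sd 40 intensity units, plus white noise of sd 5 over a base
level of 100. Shorter correlation length yields higher GLCM contrast and
entropy, so the class difference is monotone in the correlation-length gap;
setting equal scales (and equal hazards) gives a null cohort. The default
64x64 grid keeps full-cohort extraction to seconds; the clinical 512x512
is configurable.

Clinical fields are drawn so the MR grading reproduces the intended class
exactly (responders: 10% grade 5, 15% low-cellularity grade 3, else 30–95%
reduction; non-responders: reductions below 30%, 40% of them non-reductions).
Survival is exponential with class-specific hazards, censored by light
random dropout (~10% loss over follow-up) plus an administrative cut at 120
months. The default hazards target ten-year recurrence-free survival of 75%
(R) and 40% (NR). The NR value sits at the lower edge of the 40–60% band
such cohorts show because a design-stage power analysis put the log-rank
power at n = 56/16 below one half for a 75%-vs-50% separation under any
censoring pattern — a property test requiring significance in most seeds
would then be testing a coin flip. Heavier uniform-over-follow-up censoring
was rejected for the same reason (it halves the event count) and because
near-complete follow-up better matches a 10-year observational cohort.

What the phantoms do *not* emulate: anatomy (no ductal structure, no
contrast-agent kinetics), scanner effects (no beam hardening, slice
correlation, or HU calibration), inter-patient texture heterogeneity beyond
the two class distributions, and any association between texture and
survival other than through the class label. Passing tests on these cohorts
therefore demonstrate that the machinery recovers a texture signal of the
assumed form and finds none where there is none — not that the clinical
effect size is reproducible from real CT data, which are not distributed.

## Numerical choices and degenerate inputs

* GLCM normalization is exact-sum; windows with no pair at an offset skip
  that direction, and a window with no pairs at all is invalid.
* `auc632plus()` skips bootstrap replicates whose bootstrap sample or
  out-of-bag set is single-class and errors only if all are.
* AdaBoost stops early on a perfect member (it dominates the vote) or when
  the weak learner hits error >= 0.5; a first such member is kept with
  negligible weight so the ensemble is always defined.
* Per-fold and per-bootstrap seeds are derived deterministically from the
  single global seed; identical configurations give byte-identical outputs.
* Mann–Whitney AUC handles ties by midranks.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use the study-scale 56/16 cohort
at the default 64x64 grid for parameter-recovery and leakage checks (with
`B = 25` ensemble members), 16-patient cohorts for pipeline smoke runs, and
coarser 16-level quantization for most oracle-equivalence slices (two
slices run at the full 128 levels). These sizes were chosen so a complete
verification run stays in the minutes range on a single core while every
code path — including the full 128-level configuration — is exercised.

## Known limitations

* The SFS score averages the 0.632+ AUC over LOPO folds; scoring once on
  the full table is supported but not the default.
* Only 2D per-slice GLCMs are implemented (no 3D co-occurrence, no
  run-length or wavelet families).
* The outer cross-validated metrics are optimistic by construction when the
  single final subset is reused across outer folds (see above); a strict
  per-fold protocol can be assembled from the exported building blocks.
* Survival analysis is limited to KM/log-rank; no Cox regression or
  competing risks.
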