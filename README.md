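# sdtexture

Pre-treatment prediction of neoadjuvant chemotherapy (NAC) response in
locally advanced breast cancer from CT texture, with survival analysis of
the predicted cohorts.

Routine contrast-enhanced CT of a breast tumor carries micro-structural
information through partial-volume effects. `sdtexture` quantifies it with
gray-level co-occurrence matrix (GLCM) statistics and *second-derivative
texture* (SDT) — GLCM statistics of GLCM parametric maps — and uses them as
biomarkers to predict, before treatment starts, whether a patient will
respond to NAC.

## The method

For every tumor slice (ROI masked, quantized to `Ng = 128` levels), a 3x3
window slides with step 1; per window a symmetric GLCM at one-pixel offset
is computed along 0°, 45°, 90° and 135°, and eight statistics — ENT, CON,
COR, MAX, MEA, HOM, STD, ENE, e.g. entropy `ENT = -Σ p log₂ p` and contrast
`CON = Σ (i-j)² p(i,j)` — are direction-averaged onto the center pixel,
giving 8 parametric maps. Re-running the analysis on each map yields the 64
SDT features (`ENT_CON` = contrast of the entropy map); slice values are
aggregated per tumor by ROI-area weighting, for 72 features per patient.

The pipeline then:

1. standardizes features with the robust scaler `(x - median)/IQR`;
2. ranks them by mRMR (mutual-information difference form) under
   leave-one-patient-out (LOPO) cross-validation, consolidating fold
   rankings by position-wise majority and keeping the top 8;
3. selects a subset by sequential forward selection scored with the 0.632+
   bootstrap AUC, `(1-w)·AUC_app + w·max(AUC_oob, 0.5)` with
   `w = 0.632/(1 - 0.368·R)`;
4. balances each LOPO training set (SMOTE k=3 doubling of the minority +
   `B = 300` equal-size bootstrap draws of the majority) and trains one
   AdaBoost decision-tree classifier (depth 4, 150 estimators, learning
   rate 0.1) per balanced set; the held-out patient is removed *before*
   balancing, and the fold's vote fraction (share of members voting R, R
   predicted at ≥ 50%) is the prediction score;
5. reports confusion-matrix metrics and Kaplan–Meier / log-rank ten-year
   recurrence-free survival for the true and the predicted R/NR cohorts.

Because no patient CT data are distributable, the package includes a
synthetic-cohort generator (`generate_cohort()`): Gaussian random-field
tumor phantoms whose texture correlation length is class-specific, clinical
fields consistent with the modified-response (MR 1–5) grading, and censored
exponential survival. All study-scale checks run on these phantoms.

## Worked example

```r
library(sdtexture)

cfg <- run_config(
  out_dir  = file.path(tempdir(), "demo_run"),
  cohort   = cohort_config(n_responders = 10, n_nonresponders = 6,
                           slice_grid = 24, mean_slices = 3, seed = 42),
  n_keep = 3, B_sel = 5,
  balance  = balance_config(B = 8),
  ensemble = ensemble_config(n_estimators = 15),
  seed = 1)
res <- run_pipeline(cfg)

res$selection$trace
#>   size   added     score
#> 1    1     COR 0.8809968
#> 2    2     STD 0.9961433
#> 3    3 MEA_COR 0.9972961
m <- res$metrics
sprintf("accuracy %.3f sensitivity %.3f specificity %.3f AUC %.3f",
        m$accuracy, m$sensitivity, m$specificity, m$auc)
#> "accuracy 0.938 sensitivity 1.000 specificity 0.833 AUC 0.917"
```

The SFS trace shows the LOPO-averaged 0.632+ AUC as features are added: the
correlation feature alone scores 0.881, adding STD raises it to 0.996, and
the best subset is `{COR, STD, MEA_COR}`. On this small phantom cohort the
LOPO ensemble then classifies 15 of 16 patients correctly (one
non-responder missed). `res$survival` holds the KM curves and log-rank p
for the true and predicted cohorts; at 16 patients the log-rank test is
underpowered, which is why the study-scale checks below use 72.

Stage artifacts (`features.csv`, `selection.json`, `predictions.csv`,
`metrics.json`, `survival.json`, `manifest.json`) are written to
`cfg$out_dir`, and reruns with the same config are byte-identical.

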