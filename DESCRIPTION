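Package: sdtexture
Title: Second-Derivative CT Texture Biomarkers for Pre-Treatment
    Chemotherapy Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict neoadjuvant chemotherapy response of breast
    tumors from pre-treatment contrast-enhanced CT. Implements sliding-window
    gray-level co-occurrence matrix (GLCM) parametric maps and
    second-derivative texture (SDT) features (72 features per tumor),
    minimum-redundancy-maximum-relevance feature ranking under
    leave-one-patient-out cross-validation, sequential forward selection
    scored with the 0.632+ bootstrap AUC estimator, a SMOTE plus
    bootstrap-balanced AdaBoost decision-tree voting ensemble with leak-free
    leave-one-patient-out evaluation, and Kaplan-Meier / log-rank
    recurrence-free survival analysis of the true and predicted response
    cohorts. Includes a synthetic-cohort generator (correlated Gaussian
    random-field tumor phantoms with censored survival) so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
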