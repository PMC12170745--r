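Package: radsurv
Title: Zone-Wise Radiomics and Clinical Survival Modelling for Diffuse Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for comparing radiomics and
    clinical survival models in IDH-mutated lower-grade glioma. Provides a
    synthetic cohort generator (segmented two-sequence tumor volumes with
    controllable shape and run-length texture, clinical covariates, and
    Weibull proportional-hazards outcomes), peritumoral zone extraction by
    anisotropic Euclidean distance, IBSI-style shape, first-order and
    gray-level run-length (GLRLM) feature extraction, a variance /
    Spearman-correlation / LASSO-Cox feature-selection cascade, Cox model
    fitting with exact linear SHAP explanations, Harrell's and Uno's (IPCW)
    concordance evaluation with paired bootstrap model comparison, and
    log-rank-optimal risk-group stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    survival,
    glmnet,
    stats,
    utils,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
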