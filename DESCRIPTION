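Package: uroxai
Title: Explainable Boosted-Tree Diagnostics for Suspected Urolithiasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An explainable machine-learning workflow for emergency-department
    diagnosis of suspected urolithiasis. Fits gradient-boosted tree risk models
    with stratified out-of-fold evaluation (AUC with bootstrap confidence
    intervals, DeLong and paired-bootstrap model comparisons, Brier score,
    quantile calibration, held-out permutation importance); explains individual
    predictions with interventional Shapley attributions computed by background
    marginalization, including dependence curves with zero-crossing detection,
    stratified contribution tables and per-patient waterfall explanations;
    quantifies the marginal diagnostic information of sequential testing stages
    with a Shannon-entropy framework and a threshold-based resolution cascade;
    and projects threshold operating points to other baseline prevalences via
    Bayes' rule. A seeded synthetic cohort generator emulating published
    class-conditional feature summaries makes the whole pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    mgcv,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
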