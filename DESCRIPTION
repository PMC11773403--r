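Package: corticomark
Title: Analytical Validation of a Sensorimotor Cortical Pain Biomarker Signature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analytically validating a two-feature cortical pain
    biomarker: sensorimotor peak alpha frequency (PAF) estimated from resting
    electroencephalography, and corticomotor excitability (CME) change derived
    from transcranial magnetic stimulation motor maps. Implements Welch spectral
    estimation with component-space (independent component analysis) and
    sensor-region-of-interest PAF pathways, motor-map volume and area metrics
    with facilitator/depressor classification, a two-class growth mixture model
    for longitudinal pain-diary trajectories with locked posterior-probability
    labeling, a nested train/validation/test classification scheme with
    candidate-model selection and locked-model blinded prediction, ROC/AUC with
    bootstrap confidence intervals and Youden-optimal thresholds, raw-unit
    biomarker cutoffs, test-retest reliability (intraclass correlation, Cohen's
    kappa), a robustness grid over methodological choices, and a seeded
    synthetic-cohort generator emulating the full study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    e1071,
    ranger,
    xgboost,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
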