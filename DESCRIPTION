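Package: sleepagree
Title: Agreement Analysis for Contactless Sleep Trackers Against Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Epoch-by-epoch and all-night agreement analysis for validating
    contactless sleep-tracking devices against polysomnography (PSG). Implements
    simple and repeated-measures Bland-Altman limits of agreement with
    delta-method confidence intervals, regression-modeled bias and
    heteroscedastic limits with basic-bootstrap coefficient intervals,
    Shapiro-Wilk gating with a log-transform path, epoch-by-epoch sleep/wake
    classification metrics (sensitivity, specificity, Cohen's kappa,
    prevalence-and-bias-adjusted kappa, d-prime, pooled ROC/AUC), hypnogram
    summary variables (sleep onset latency, wake after sleep onset, total sleep
    time, sleep efficiency), overnight heart-rate and breathing-rate profile
    concordance with covariate regression, clock-offset alignment by movement
    cross-correlation, and a Fisher-z sample-size calculator for correlation
    confidence intervals. A calibrated synthetic cohort generator (Markov-chain
    hypnograms, stage-dependent vitals, a configurable device error model and a
    three-scorer panel) makes the full pipeline exercisable without access to
    any proprietary study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    lme4,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
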