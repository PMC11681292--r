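Package: shiftmon
Title: Longitudinal Model-Shift Monitoring for Clinical Risk Prediction Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monitors deployed clinical risk prediction models for temporal
    model shift. Provides per-period discrimination metrics (AUROC with
    Hanley-McNeil standard errors and pairwise Z-tests, average precision),
    probability recalibration by Platt scaling with quantile-binned
    reliability curves and expected/maximum calibration error (ECE/MCE),
    calibration-shift flagging, and decision-impact evaluation (threshold
    selection balancing over- and underdiagnosis, five-category alert
    classification, decision curve analysis with net benefit, incidence
    standardization, and bootstrap comparison of decision curves across
    periods). A seeded synthetic scored-cohort simulator with a binormal
    latent-score model and injectable miscalibration provides a
    parameter-recovery surface for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
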