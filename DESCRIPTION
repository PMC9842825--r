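Package: mmroc
Title: Multi-Modal AI Score Fusion and Reader-Study Benchmarking for
    Breast Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating multi-modal diagnostic AI in breast cancer
    screening. Fuses continuous suspicion scores from two imaging modalities
    (digital mammography and automated 3D breast ultrasound) by normalized
    weighted averaging with a grid search over fusion weights, compares
    single- and multi-modal performance with empirical ROC curves, the
    DeLong paired AUC test and maximum-Youden operating points, and
    benchmarks against simulated radiologist reading strategies (single
    reader, either-recall double reading, four-reader majority panel) with
    stratified bootstrap confidence intervals. Includes a synthetic cohort
    generator with class-conditional correlated binormal scores and
    calibrated ordinal BI-RADS readers, so the full pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
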