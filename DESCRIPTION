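Package: mpecost
Title: Cost-Effectiveness of Tumor-Marker Panels for Diagnosing Malignant
    Pleural Effusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates clinical cohorts of malignant and benign pleural
    effusion patients with heavy-tailed tumor-marker concentrations, fits a
    stacked ensemble of five machine-learning classifiers over every
    non-empty subset of eight (fluid, analyte) tumor markers, prices each
    panel with an additive cost model, and scores the accuracy/cost
    trade-off with a weighted comprehensive score (C-score) including a
    weight sweep, median-based quadrant segmentation and anchor-marker
    outlier flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
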