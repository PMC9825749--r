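Package: mbtraj
Title: Microbiome Maturation Trajectories, Anomaly Detection and
    Intervention Simulation for Longitudinal Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives a reference microbiome trajectory (Microbiome
    Maturation Index versus time) from longitudinal feature-abundance
    tables, with compositional log-ratio preprocessing and data-driven
    denominator selection, alpha diversity and low-dimensional embedding
    exploration, two-group differential feature analysis, statistical
    comparison of group trajectories by linear models and spline
    permutation tests, longitudinal anomaly detection (prediction-interval,
    low-pass rolling-window and Isolation Forest detectors) with
    Shapley-value outlier explanation, and model-space intervention
    simulation that restores anomalous samples toward the reference
    trajectory. Ships a seeded synthetic-data generator with known ground
    truth and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    xgboost,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
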