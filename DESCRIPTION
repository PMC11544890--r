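Package: holodcc
Title: Label-Free Differential Leukocyte Counts from Quantitative Phase Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for differential cell counts
    (DCC) from digital holographic microscopy (DHM) recordings of blood and
    milk leukocytes. Converts multi-frame quantitative phase recordings into
    single-cell patches (median background subtraction, threshold
    segmentation, area filtering), computes a 24-dimensional hand-crafted
    morphological feature catalog per cell, balances labeled training data
    with SMOTE, trains and tunes k-nearest-neighbor, random-forest and
    support-vector classifiers, and scores them with confusion matrices,
    one-vs-rest sensitivity/specificity, leave-one-subject-out validation
    and per-sample composition comparisons (MAE/MRE/RMSE) against a
    reference method. A seeded synthetic-data module generates annotated
    phase recordings and longitudinal study designs so every stage is
    testable without access to instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    grDevices,
    tools,
    ggplot2,
    jsonlite,
    matrixStats,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    class,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
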