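Package: frnet
Title: Fast Ripple Network Analysis for Epilepsy Surgery Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intracranial EEG fast ripple (FR) event
    catalogs in patients evaluated for resective epilepsy surgery. Starting
    from per-contact FR event times, contact coordinates and resection masks,
    the package computes event resection ratios, spatial rate-distance
    network radii, mutual-information (MI) networks between FR event trains
    with weighted graph metrics (characteristic path length, clustering
    coefficient, local efficiency), directed FR propagation edges, and a
    diagnostic layer (ROC curves, Youden's J operating points, confusion
    matrices with exact binomial confidence intervals, and reflex testing)
    that classifies post-operative seizure outcome. A synthetic SEEG cohort
    generator with coupled point-process event trains supports testing and
    calibration of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
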