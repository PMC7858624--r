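Package: supercohort
Title: Cohort Aggregation for Histopathology Cancer Detection Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies morphological similarity between cancer cohorts from the
    cross-cohort behaviour of patch-level classifiers, groups cohorts into
    super-cohorts by Ward hierarchical clustering of similarity-matrix columns,
    trains one cancer-detection model per super-cohort, and selects partitions
    that trade the number of models against detection performance under a
    confidence-interval gate. Includes a synthetic multi-cohort slide generator
    with a planted similarity hierarchy so the full analysis runs at desk scale,
    balanced patient-exclusive sub-dataset resampling, slide-level
    likelihood-ratio aggregation of patch probabilities, and AUROC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phytools,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    uwot,
    yaml
Config/testthat/edition: 3
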