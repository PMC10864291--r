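Package: geneflight
Title: Cuckoo-Search Gene Selection and a Weighted Convolutional Network
    for Two-Class Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for two-class classification of gene-expression
    matrices (tumor versus normal microarray profiles and similar data):
    per-gene Z-score normalization with train/test separation, wrapper gene
    selection by an improved Levy-flight cuckoo search with a geometrically
    decaying step-size schedule, a small from-scratch "weighted"
    convolutional neural network classifier with exact analytic gradients,
    and the standard evaluation protocol (stratified 70/30 split, stratified
    k-fold cross-validation, confusion-matrix metrics, ROC/AUC). Includes a
    seeded generator of synthetic microarray-like datasets with a planted
    informative gene subset so the whole pipeline is testable without
    external downloads.
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
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
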