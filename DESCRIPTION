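Package: bovwscreen
Title: Bag-of-Visual-Words Screening for Diabetic Retinopathy Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end bag-of-visual-words (BoVW) pipeline for automated
    screening of referable diabetic retinopathy in colour fundus images.
    Detects scale-space points of interest, learns per-lesion visual
    codebooks by k-means (or random selection), encodes images by hard
    assignment with sum pooling, trains maximum-margin detectors for bright
    lesions (hard exudates) and red lesions (microaneurysms and
    haemorrhages), and fuses the two detectors with an OR rule so an image
    is called normal only when both agree. Evaluation follows a
    cross-dataset protocol (train on one cohort, test on another) with
    ROC/AUC, sensitivity and specificity reporting. A synthetic fundus
    generator provides labelled two-cohort benchmarks with controllable
    domain shift (resolution, colour gain, JPEG re-encoding).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    e1071,
    EBImage,
    png,
    yaml,
    jsonlite,
    withr,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
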