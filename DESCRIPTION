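Package: ClotQuant
Title: Machine-Learning Histological Quantification of Ischemic Stroke Clots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trainable pixel classification for the histological
    quantification of acute ischemic stroke thrombi on H&E-stained
    whole-slide images. Sliding-window texture features feed kernel
    support vector machine pixel classifiers: an exclusion model
    (background / tissue / artefact) composed with a classification model
    (red blood cells / white blood cells / fibrin) yields per-slide
    composition percentages and RBC-rich / mixed / fibrin-rich clot
    categories. Includes a synthetic H&E clot-slide generator with
    pixel-level ground truth, a representative-region color-threshold
    comparator emulating the manual reference workflow, and the
    method-agreement and clinical-correlation statistics (Bland-Altman
    limits of agreement, Spearman rank correlation, Pearson chi-squared
    association with the hyperdense artery sign).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    digest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
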