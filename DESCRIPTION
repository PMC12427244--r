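Package: sweatvoc
Title: Chemometric Classification of Sweat Volatilome Profiles from GC-MS
    and Electronic-Nose Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dual-platform chemometric pipeline for discriminating disease
    and control groups from the sweat volatilome. One arm curates gas
    chromatography-mass spectrometry (GC-MS) peak tables into a retention-time
    feature matrix, imputes missing peaks, normalizes (autoscaling, Pareto,
    quantile and related transforms), screens features with the Wilcoxon
    rank-sum test, and projects samples with PCA or NIPALS PLS-DA with
    variable-importance-in-projection (VIP) scores. The other arm extracts
    Max-Min response amplitudes from 14-channel electronic-nose transients and
    removes class-orthogonal drift with orthogonal signal correction (OSC)
    before PCA. Both arms feed linear discriminant analysis, penalized
    logistic regression, linear support-vector machine and k-nearest-neighbour
    classifiers evaluated by stratified k-fold cross-validation with pooled
    confusion matrices, sensitivity/specificity/precision/F1 panels and
    ROC/AUC, plus a permutational MANOVA of group separation. A synthetic-data
    module emulates both data types so the whole pipeline is testable without
    instrument access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    pROC,
    e1071,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
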