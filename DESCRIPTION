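Package: ecfam
Title: Multi-Label Enzyme Family Class Prediction from Functional Domain Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Predicts the family classes of enzymes (the first digit of the
    EC number, classes 1-7) from their functional-domain annotations.
    Proteins are encoded into compact L-dimensional vectors built from the
    class-conditional distribution of domain terms in a training set, and
    classified with a random k-labelsets (RAKEL) ensemble of label-powerset
    classifiers over random forest or support vector machine base learners.
    Includes the full multi-label evaluation suite (aiming, coverage,
    accuracy, absolute true/false, per-class measures with AUROC/AUPR),
    leakage-safe general and stratified ten-fold cross-validation, grid
    search, a synthetic corpus generator for download-free testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    kernlab,
    methods,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
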