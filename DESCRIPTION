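Package: msnpain
Title: Morphometric Similarity Networks for Pain-State Discrimination and
    Pain-Intensity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds individual-subject morphometric similarity networks (MSN)
    from multimodal regional brain features and functional connectivity
    networks (FCN) from region-averaged BOLD series, and implements three
    case-control discrimination models (univariable mean-similarity testing
    with replication, per-region logistic scoring, and a PCA-logistic
    network classifier with Haufe activation-pattern back-projection), a
    PCA-LASSO regression of pain intensity with leave-one-out penalty
    selection, a weighted-correlation structural/functional ensemble, and a
    discovery/validation evaluation harness. Includes a synthetic
    case-control cohort generator with planted region and edge effects so
    every stage can be tested against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
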