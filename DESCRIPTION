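Package: apogee
Title: Bootstrap-Aggregated Logistic Model Trees for Mitochondrial
    Missense Pathogenicity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Meta-prediction of the pathogenicity of human mitochondrial
    non-synonymous variants from tables of upstream predictor scores. The
    classifier is a two-class logistic model tree (a decision tree with
    LogitBoost-fitted additive logistic models at its leaves) aggregated
    over 100 class-balanced bootstrap resamples, with out-of-bag
    probability averaging and a strict mean-probability > 0.5 call rule.
    Also provides the feature dichotomization rules used to harmonize
    heterogeneous predictor outputs, per-site coevolution summaries from
    mutual-information Z-score matrices, a confusion-matrix metric suite
    (sensitivity, specificity, accuracy, precision, FDR, MCC,
    misclassification rate, ROC/AUC), exhaustive missense enumeration
    under the vertebrate mitochondrial genetic code, and a synthetic-data
    generator that emulates two-class score tables with per-predictor
    missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
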