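Package: bitterspec
Title: Bitterness Prediction Directly from Experimental Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether a compound tastes bitter directly from its
    experimental mass spectrum (EI-MS or positive-mode ESI-MS/MS), without
    intermediate structure annotation. Provides parsers for MassBank record
    and NIST MSP formats, fixed-width m/z binning featurization with three
    peak-descriptor strategies, compound-level stratified train/test splits
    that prevent spectrum leakage, tree-ensemble classifiers (random forest
    and gradient boosting) with grouped cross-validated grid search, a naive
    prevalence baseline, confusion-matrix metrics with averaged ROC and
    precision-recall curves over repeated splits, majority-vote aggregation
    of per-spectrum predictions into compound labels, and a synthetic
    class-conditional fragment-spectrum generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tools,
    methods,
    stats,
    utils,
    S4Vectors,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'spectra-io.R'
    'featurize.R'
    'dataset.R'
    'classifier.R'
    'evaluation.R'
    'prediction.R'
    'synthetic.R'
    'pipeline.R'
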