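Package: forestability
Title: AUC Hyper-Stability Benchmarking of Random Forest Implementations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks ensemble-classifier backends for short biomarker
    signature discovery by measuring not only their mean validation AUC but
    the reproducibility of that AUC across repeated model fits. For every
    candidate signature and balanced train/validation resampling, replicate
    models are trained and the coefficient of variation of their AUCs is
    computed; hyper-stability (HRS/HSS) and relative-stability (RRS/RSS)
    scores summarise how often an implementation reproduces exactly (or
    nearly) the same AUC. Includes rank-based feature selection with
    Kuncheva and Spearman stability indices, random signature planning,
    stratified balanced resampling, a pluggable forest-backend contract with
    out-of-bag tree-count tuning, and a synthetic RPKM-like expression-data
    generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    ranger,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
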