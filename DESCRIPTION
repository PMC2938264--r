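Package: mirscreen
Title: Blood-Borne miRNA Profiling for Case-Control Screening Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of probe-level miRNA microarray
    case-control studies in whole blood. Generates Geniom-style arrays
    (many replicate spots per probe) with noise calibrated to observed
    biological-replicate statistics, performs background correction,
    median summarization and glog (arsinh) variance-stabilizing
    normalization, computes per-miRNA t-test/Benjamini-Hochberg and ROC
    statistics, runs leakage-free repeated k-fold cross-validated SVM
    classification with t-test feature filtering inside each training
    fold plus permutation-null validation, and evaluates screening
    utility (PPV/NPV) under arbitrary disease prevalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    e1071,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
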