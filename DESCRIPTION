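Package: plasmaLncDx
Title: Circulating lncRNA Biomarker Panels and Risk-Score Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A multiphase case-control pipeline for discovering and
    validating circulating long non-coding RNA (lncRNA) biomarker panels
    in plasma, modelled on hepatocellular carcinoma diagnosis. Implements
    microarray screening filters (differential tests, up-in-case with
    down-post-operation intersection, intensity and fold filters), a
    qPCR training-set panel filter, an indicator-based risk score
    function with control-percentile positivity thresholds and Youden or
    midpoint cutoff selection, ROC/AUC and confusion-matrix diagnostics
    over training, validation and double-blind phases, and paired
    pre/post-operative expression dynamics with a secondary-increase to
    metastasis association test. Includes a synthetic cohort generator
    so the whole study design is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort.R'
    'screening.R'
    'panel.R'
    'postop.R'
    'roc.R'
    'riskModel.R'
    'pipeline.R'
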