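Package: tracseq
Title: Whole-Blood RNA-Seq Biomarker Discovery for Coronary Artery Disease
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested reusable pipeline for discovering and evaluating
    whole-blood RNA biomarkers of coronary artery disease (CAD) from bulk
    RNA-seq. Implements RPKM normalization, a multi-stage differential
    expression filter cascade (expression floor, uncorrected t-test,
    fold-change and expression-percentile filters) for transcripts
    associated with CAD (TRACs), composite transcript scoring with
    diagnostic evaluation (empirical ROC C-statistic, confusion metrics),
    PLS-DA with stratified cross-validation, cell-type marker indices,
    hypergeometric gene-set over-representation, cross-cohort symbol
    matching, and the cell-mixture arithmetic that translates regulatory
    T-cell (Treg) depletion into expected transcript fold changes. Ships a
    synthetic whole-blood cell-mixture cohort generator with planted Treg
    depletion and TRAC down-regulation for end-to-end parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mixOmics,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
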