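Package: crpcPanel
Title: Hormone-Treatment Response Gene Panels for Prostate Cancer from
    Bulk and Single-Cell Transcriptomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives and evaluates castration-resistant prostate cancer
    (CRPC) hormone-treatment-response gene panels from combined bulk and
    single-cell RNA-seq data. Provides cohort stratification by phenotype
    rules, a moderated-t differential-expression screen, sum-of-z-score
    module and panel scoring, subgroup-featured-gene selection with an
    expression-fraction filter, a permutation-tested ligand-receptor
    communication intensity between cell subgroups, and ROC/correlation
    panel evaluation, together with negative-binomial single-cell and
    Gaussian bulk cohort simulators with planted ground truth for
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, SingleCell, GeneExpression, DifferentialExpression
RoxygenNote: 7.3.3
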