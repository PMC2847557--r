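Package: ampliBias
Title: Detection of Probe Sets Mis-Represented by Two-Cycle RNA
    Amplification on 3'-Biased Expression Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical workflow for comparing RNA amplification and
    labelling protocols (one-cycle, two-cycle, IVT-Express) on short
    oligonucleotide expression arrays. Provides probe-level preprocessing
    (quantile normalization and median-polish summarization), a per-probe-set
    5'/3' probe-position bias statistic, a studentised-residual classifier
    with replicate and cross-comparison consensus that flags probe sets over-
    or under-amplified by two-cycle labelling, replicate and protocol
    concordance measures (R-squared, PCA, median-of-array relative expression,
    fold summaries), and a fold-change plus Benjamini-Hochberg FDR
    differential-expression concordance analysis. A seeded probe-level
    simulator with planted ground truth makes every stage verifiable without
    array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Microarray, Preprocessing, QualityControl, GeneExpression,
    DifferentialExpression
RoxygenNote: 7.3.3
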