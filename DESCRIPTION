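Package: crossnorm
Title: Cross Normalization for Expression Data with Global Shifts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Normalization of two-condition gene expression matrices in which
    transcript abundance shifts globally between conditions (for example
    transcriptional amplification in tumours). Conventional column-wise
    normalizers such as quantile normalization force every array onto one
    reference distribution and thereby flatten condition-wide expression
    differences; cross normalization concatenates matched control and disease
    profiles into single cross-columns before normalizing, so between-condition
    differences survive. The package provides the pairwise and general
    (unpaired) cross-normalization variants around exchangeable base
    normalizers (quantile, median-baseline scaling, cyclic loess), fold-change
    plus t-test differential expression calling, overlap and direction-overlap
    consistency statistics, confusion-matrix benchmarking metrics (precision,
    recall, FPR, F1, MCC), a paired-simulation engine with injected
    differentially expressed genes, spike-in profile construction, and
    trend-shape categorization for titration series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
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
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Normalization, Preprocessing, DifferentialExpression, Microarray,
    GeneExpression
RoxygenNote: 7.3.3
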