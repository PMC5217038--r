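Package: stemomics
Title: Integrated Metabolome-Transcriptome Analysis of Stem-Like Cancer Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for paired metabolomics and
    transcriptomics comparisons of parental versus stem-like (stress-selected)
    cancer cells. Provides targeted-metabolite statistics with protein
    normalization and Z-score profiling, two-class PLS-DA fitted by NIPALS with
    VIP scores, cross-validated Q2, Hotelling's T2 ellipse and repeated
    permutation validation, quantile normalization and (random-variance)
    differential expression with Kolmogorov-Smirnov gene-set enrichment,
    differential co-expression network construction over pathway gene sets,
    gene-metabolite correlation clustering, and a synthetic-data generator that
    plants known fold changes and condition-specific co-expression modules so
    every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
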