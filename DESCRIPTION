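Package: erenorm
Title: Expressed Repeat Elements as Reference Targets for RT-qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of expressed repetitive elements (EREs)
    as reference targets for RT-qPCR normalization. Implements candidate
    discovery from repeat consensus libraries (copy-number, expressed-hit and
    conservation filters plus conserved-region delineation), amplification
    efficiency estimation from standard dilution series, efficiency-corrected
    relative quantification, the geNorm expression-stability algorithm
    (pairwise variation, M-values, stepwise exclusion ranking, V curve),
    cross-experiment rank aggregation by Borda count and cross-entropy Monte
    Carlo minimisation of a weighted Spearman footrule objective, and
    normalization-bias comparison of reference sets. Synthetic Cq and sequence
    generators with recorded ground truth make every stage testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    methods,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
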