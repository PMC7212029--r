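Package: wntstrat
Title: Molecular Stratification of Colorectal Tumours by Wnt Ligand Dependence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stratify colorectal tumours into Wnt ligand-dependent (LD)
    and ligand-independent (LI) classes from multi-omic data. Implements
    mutation- and fusion-based molecular ground truthing (RSPO2/3 fusion
    junction detection from RNA-seq reads, Wnt driver mutation interpretation,
    outlier-expression RSPO-high calling), differential expression of Wnt
    negative-regulator genes with weighted Kolmogorov-Smirnov gene-set
    enrichment, DNA methylation-expression coupling analysis with
    CIMP-stratified comparisons, and derivation of a single-gene AXIN2
    expression threshold biomarker via ROC analysis. A synthetic multi-omic
    cohort simulator with planted ground truth supports end-to-end validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
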