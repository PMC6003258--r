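Package: heterex
Title: Heterosis and Inheritance-Mode Analysis for Parent-Hybrid Trio
    RNA-Seq Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing heterosis in a two-parent/F1-hybrid trio
    design. Computes mid-parent and high-parent heterosis with significance
    tests from replicated trait tables, identifies differentially expressed
    genes between lines with an exact conditional negative-binomial test and
    Benjamini-Hochberg FDR control, decomposes per-gene expression into
    composite additive and dominance effects under a randomized-block model,
    classifies each gene's mode of inheritance from the dominance ratio
    Hp = [d]/[a], performs hypergeometric term enrichment against
    user-supplied gene-set maps, and colocalizes candidate genes with QTL
    intervals. Includes a negative-binomial trio simulator with known
    ground-truth effects so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, DifferentialExpression, GeneExpression,
    Genetics, Software
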