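Package: mutscape
Title: Off-Target Mutation Profiling for Adenine Base Editors in Plant
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for genome- and transcriptome-wide
    off-target mutations induced by adenine base editors (ABEs) in
    transgenic plant cohorts.  Implements multi-caller variant consensus
    filtering with background subtraction, an exact binomial test for
    residual homozygous background loci, sgRNA-dependent target-site
    search under full-spacer and seed-constrained mismatch budgets,
    strand-collapsed mutation-spectrum and genomic-region enrichment
    statistics, T-DNA integrity and copy-number assessment with
    sibling-plant stage attribution, RNA A-to-G editing-ratio analysis
    with motif matrices, and a flanking-window statistic for clustered
    editing.  A synthetic cohort generator with a full truth table makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    SummarizedExperiment,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
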