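Package: rhemiseq
Title: Reciprocal Hemizygosity Sequencing (RH-seq) Analysis of Pooled
    Transposon Insertion Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for sequencing-based reciprocal hemizygosity (RH-seq)
    screens in which pooled F1 hybrid hemizygotes, generated by Mos1
    transposon mutagenesis of either parental strain, are competed under a
    selective condition and read out by transposon insertion-site
    sequencing. Implements demultiplexing and transposon-junction extraction
    from raw reads, SNP-substituted pseudogenome construction for mapping
    the non-reference parent's reads, exact unique mapping of genomic
    flanks, single-linkage collapsing of insertion sites, per-insertion
    selection effects (log2 control/treatment abundance ratios), per-gene
    two-sample Mann-Whitney reciprocal hemizygosity tests with
    Benjamini-Hochberg correction, and a full synthetic-experiment
    generator with machine-readable ground truth for end-to-end
    verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
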