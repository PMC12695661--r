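Package: eureg
Title: Regulation Classification and Regulatory Annotation for Nascent
    Transcription (EU-seq) Experiments
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and classifying transcriptional
    regulation from metabolic-labeling nascent RNA sequencing (EU-seq)
    after acute perturbations. Implements representative-transcript
    selection, elongation-aware counting windows, strand-aware fragment
    counting with exclusion regions, TPM and expression filters,
    median-of-ratios size factors with asymmetry-corrected log2 fold
    changes, a fold-change regulation-class taxonomy with small-class
    merging and replicate-reproducibility filtering, upstream antisense
    transcription calling, gene-set overlap enrichment statistics,
    promoter CTCF peak geometry and motif-orientation annotation,
    anchored Pol II ChIP normalization, ATAC differential accessibility
    with peak-height quartile stratification, and a fully seeded
    synthetic-data generator for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
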