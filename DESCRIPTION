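Package: txomeatlas
Title: Transcriptome Characterization from Assembled Transcripts, Splice
    Junctions and Expression Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream characterization of a multi-tissue plant
    transcriptome from assembler-level inputs: reconciliation of assembled
    transcripts against CDS-only gene models (complete/partial/novel
    labels, novel transcribed regions, UTR boundaries, upstream ORFs), an
    expression atlas (expressed/constitutive/housekeeping/tissue-specific
    calls, expression tiers, the tau tissue-specificity index, tissue
    clustering), splice-junction based alternative-splicing event
    classification (intron retention, exon skipping, alternative 5'/3'
    splice sites), and category over-representation statistics with
    Benjamini-Hochberg FDR control. Includes a synthetic-data generator
    that plants every feature class with a machine-readable truth table so
    the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
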