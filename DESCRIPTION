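Package: regonset
Title: Inferring Direct Transcription-Factor Targets from Developmental
    Timecourse Expression and ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for identifying the direct target genes
    of a transcriptional regulator switched on during a developmental
    timecourse. Dynamically expressed genes are filtered and classified by
    Pearson correlation with the regulator across four sorted cell
    populations on two array platforms, ChIP-Seq peaks are repeat-filtered,
    partitioned into early-shared and late-only classes and annotated to
    genes by promoter/intragenic/intergenic rules, IUPAC consensus motifs
    are scanned in peak cores, and knockout differential expression is
    intersected with binding and correlation evidence to produce
    positively- and negatively-controlled target sets with hypergeometric
    overlap statistics. A synthetic-data generator with recorded ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    limma,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
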