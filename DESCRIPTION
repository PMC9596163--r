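Package: regscreen
Title: Rule-Based Screening for Co-Bound Target Genes at Active Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying candidate target genes that are
    co-bound by multiple chromatin regulators (e.g. a transcription factor and
    chromatin remodelers) at active regulatory elements, and ranking them by
    cell-type specificity of expression. Peak sets (BED) are intersected with
    an in-house, oracle-tested genomic-interval algebra; regulatory elements
    are classified as active, repressed or poised promoters or enhancers from
    histone-mark co-occurrence (H3K4me3, H3K27ac, H3K4me1, H3K27me3); common
    regions at active promoters are assigned to expressed protein-coding genes
    within a configurable window of the promoter midpoint; and candidates are
    ranked by a pseudocounted log-ratio specificity score. A synthetic-data
    generator plants targets in a toy peak landscape with a machine-readable
    truth manifest so every stage of the screen is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    BiocGenerics,
    IRanges,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
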