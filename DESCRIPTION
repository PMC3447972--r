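Package: cenmisloc
Title: Genome-Wide Quantification of CENP-A Mislocalization from ChIP-chip
    Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for spike-in-normalized ChIP-chip tiling
    array data that quantifies promiscuous incorporation of the centromeric
    histone H3 variant CENP-A outside centromeres. Provides absolute signal
    quantification against exogenous spike-in controls, a global fold-change
    estimator, threshold-based calling of enriched chromatin domains,
    hypergeometric testing of centromere-proximal spatial enrichment,
    expression-stratified TSS-aligned metagene profiles with confidence
    intervals, moving-average occupancy-versus-expression curves, and
    percent-input ChIP-qPCR summaries. A seeded synthetic-data generator
    emulates a small three-chromosome fission-yeast-scale genome with
    planted enrichment domains and transcription-coupled histone depletion
    so that every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
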