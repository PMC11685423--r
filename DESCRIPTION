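Package: distalreg
Title: Classification and Evidence Integration for Distal Regulatory Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies distal H3K27ac peaks into six enhancer classes from
    H3K4me1 proximity and strand-resolved RNA-seq evidence, and layers
    orthogonal evidence on each region: transcription-factor binding sites,
    capped (RAMPAGE) transcription, reporter-assay activity, Hi-C chromatin
    loops and sequence conservation. Includes pseudo-replicate peak
    reproducibility filtering, local/distal partitioning, multi-sample
    intersection (upset) tables, mappability-masked interval shuffling for
    control regions, reference-point and scaled-region signal metaprofiles
    with a boundary-enrichment statistic, tissue-specific differential
    expression set logic, cross-inbred homolog conservation flows, small-RNA
    size/strand-bias analysis, telomere repeat counting, and a deterministic
    synthetic-data generator with planted truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
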