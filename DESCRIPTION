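Package: chromtransit
Title: Chromatin-State Transition Statistics for Paired Differentiation Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream statistics for comparing the regulatory genome of two
    differentiation stages: permutation-null enrichment of chromatin-state
    transitions on a fixed 200-bp genomic grid, association of transitions
    with nearby differential gene expression and with differential
    chromatin accessibility (Fisher exact test triplets with ratio-based
    classification), integration of motif enrichment Z-scores, footprint
    enrichment and transcription-factor expression into cell-type-specific
    TF activity calls, rule-based assembly of a TF-TF regulatory network,
    and marker-panel similarity against reference expression profiles.
    Includes a synthetic-data generator that plants known signal in every
    input so the whole pipeline can be validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    IRanges,
    optparse
Config/testthat/edition: 3
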