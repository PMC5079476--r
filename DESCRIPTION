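Package: seqcor
Title: Correlation-Based Comparison of Sequencing Experiments Against
    Reference Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds reference compendia from processed high-throughput
    sequencing outputs (RNA-seq gene expression tables, ChIP-seq peak
    files, CAGE peak files with expression scores), projects a user
    sample into a compendium's feature space, computes Pearson
    correlations between the user sample and every reference
    experiment, orders experiments by agglomerative hierarchical
    clustering of the correlation matrix, and exports clustered
    correlation heatmaps and ranked correlation tables. Includes a
    synthetic-compendium generator with planted correlation structure
    for benchmarking, and a command-line interface wiring the steps
    together.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
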