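Package: rloopr
Title: R-Loop Calling from Strand-Specific ssDNA Sequencing Coverage
Version: 0.1.0
Authors@R:
    person("Maintainer", "rloopr", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects R-loops genome-wide from strand-specific single-stranded
    DNA sequencing (spKAS-seq-style) data as genomic bins with statistically
    imbalanced read density between the plus and minus strands. Implements
    sliding-window candidate selection over KAS-seq peaks with blacklist
    exclusion, an exact binomial strand-imbalance test with Benjamini-Hochberg
    correction, threshold filtering on density and log2 strand ratio, and
    direction-aware merging of significant bins into R-loop calls. Includes
    perturbation-response analysis (RNase H dose response, transcription
    inhibitor three-type classification), genomic annotation and metagene
    profiling, binned Pearson correlation of signal tracks, a synthetic-data
    generator that plants R-loops and transcription bubbles with known truth,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
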