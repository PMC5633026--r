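Package: medipdiff
Title: Differential DNA Methylation Analysis for MeDIP-seq Experiments
Version: 0.1.0
Authors@R: person("medipdiff", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-group differential-methylation analysis of
    methylated-DNA immunoprecipitation sequencing (MeDIP-seq) data:
    read quality filtering, CpG-island detection by sliding-window
    GC/CpG-observed-over-expected criteria, windowed genome and metagene
    coverage profiling, per-group peak calling, cross-group peak merging
    by the reciprocal 50%-of-shorter-peak rule, chi-square testing of
    in-peak read counts with Benjamini-Hochberg false-discovery-rate
    control and fold-change filters, DMR-to-gene annotation, and qPCR
    2^-ddCt expression concordance. Includes a seeded synthetic-study
    generator emulating a two-breed, three-replicate paired-end MeDIP-seq
    design for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    S4Vectors,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
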