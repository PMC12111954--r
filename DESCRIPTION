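Package: synfrac
Title: Synteny-Based Fractionation and Genome-Stability Analysis of
    Polyploid-Derived Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying genome stability after an ancient
    whole-genome duplication from gene collinearity. Detects collinear
    (synteny) blocks between and within genomes by gap-penalized chaining
    of homologous gene pairs in gene-rank coordinates, estimates
    synonymous distances with the Nei-Gojobori (1986) pathway-counting
    method, classifies blocks as orthologous or paleo-duplicated by their
    Ks, builds a reference-anchored multi-genome alignment table, and
    derives per-chromosome and per-branch gene-loss statistics (including
    Dollo-parsimony branch assignment, subgenome partitioning by
    differential retention, and an ordinal-trend test), tandem gene
    clusters, and contingency-table enrichment tests. Ships a genome
    evolution simulator (tetraploidization, chromosome fusions,
    branch-specific fractionation, inversions, tandem bursts, sequence
    divergence to prescribed synonymous distances) with complete ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
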