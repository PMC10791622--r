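Package: genomovaR
Title: Delimiting Genomovars and Strains from ANI Distributions and Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting sub-species units (genomovars and strains) in
    bacterial populations from genome collections and companion metagenomes.
    Implements fragment-based average nucleotide identity (ANI) estimation,
    detection of the intra-species ANI discontinuity by binned depletion
    statistics and bootstrapped kernel-density extrema, threshold-based
    genomovar and strain clustering with linkage diagnostics, reciprocal
    best-hit orthology with core single-copy gene extraction and allele
    dereplication, competitive metagenomic read recruitment with per-genomovar
    relative abundance profiles, and extrapolation of total genomovar richness
    from leave-genomes-out accumulation curves with prediction intervals.
    Includes a synthetic population generator with a complete truth manifest
    so that every stage is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
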