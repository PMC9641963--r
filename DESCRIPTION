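Package: hapdup
Title: Segmental Duplication, Collapsed-Repeat and Trio Mutation-Rate Analysis for Haplotype-Resolved Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for characterising haplotype-resolved
    genome assemblies: filtering of self-alignment segmental duplications
    (repeat-mask and high-copy interval-graph filters, divergence-to-age
    conversion), duplicated-gene calling from spliced transcript
    multi-mapping, a negative-binomial-emission hidden Markov model that
    decodes copy number from binned read depth to find collapsed
    duplications, trio-based de novo germline mutation-rate estimation with
    callability and false-negative-rate correction, classification of the
    heterozygosity spectrum between two haplotype assemblies, and composite
    literature-evidence scoring of disease-gene candidates. Includes a
    synthetic-data generator that plants duplications, genes, collapses,
    de novo mutations and structural variants with machine-readable ground
    truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
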