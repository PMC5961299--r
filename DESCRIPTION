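Package: scafanchor
Title: Anchoring Scaffold Assemblies onto Reference Chromosomes with
    Conserved-Element Alignments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps a scaffold-level genome assembly onto a chromosome-level
    reference of a related species using a databank of highly conserved
    DNA elements (HCE) as alignment anchors.  HCE are aligned to both
    genomes with a built-in seed-and-extend local aligner, filtered to
    elements that place uniquely and near-perfectly on the reference and
    uniquely on the target, and the resulting anchors are chained into
    co-linear blocks and netted into a per-chromosome hierarchy that
    assigns, orders, and orients target scaffolds.  Includes UCSC-style
    PSL/chain/net readers and writers, an intersecting-fraction statistic
    for comparing two mappings, scaffold summary statistics (N50, median,
    totals), and a synthetic genome-pair simulator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
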