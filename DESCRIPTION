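Package: profscreen
Title: Phylogenetic Profiling, Co-Occurrence Screening and Gene-Neighborhood
    Co-Localization for Prokaryotic Genome Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds protein-family presence/absence profiles across a
    collection of prokaryotic genomes from precomputed domain-hit tables,
    screens every family for over- or under-representation between
    anchor-positive and anchor-negative genomes with an exact two-sided
    hypergeometric test under Benjamini-Hochberg false-discovery-rate
    control, and classifies anchor-partner gene-neighborhood co-localization
    by intergenic distance and strand orientation (divergent, convergent,
    tandem).  Includes a seeded synthetic genome-collection generator with a
    ground-truth manifest so every pipeline stage is testable at desk scale,
    and exporters for summary tables and iToL binary ring annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    jsonlite,
    yaml,
    ape,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
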