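Package: metboxr
Title: Comparative-Genomics Reconstruction of the MetJ Repressor Regulon
Version: 0.1.0
Authors@R: person("metboxr", "developers", role = c("aut", "cre"),
    email = "metboxr@example.org")
Description: Builds palindromic information weight matrices from MetJ
    operator (metbox) sequences, scans strand-aware 400-bp gene upstream
    regions for tandem arrays of 8-bp boxes under consensus-derived bit-score
    thresholds, refines the matrix by a two-stage bootstrap over
    representative species, classifies cross-species conservation of operator
    regions, and summarizes regulon membership per gene family and taxonomic
    order. Includes a synthetic-cohort generator with planted sites and known
    truth so every pipeline stage can be benchmarked without genome
    downloads, plus a small beta-galactosidase reporter-assay calculator
    (Miller units and repression ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
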