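Package: bsamapr
Title: Bulked-Segregant Mapping of Dominant Mutations by Delta SNP-Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping monogenic mutations from two-bulk
    whole-genome sequencing of segregating F2 populations. Computes
    per-variant SNP-index and delta SNP-index statistics from allele
    depths, smooths them in sliding genomic windows, attaches
    Monte-Carlo confidence thresholds that account for finite bulk
    size and read depth, and calls candidate regions. Includes a
    seeded F2 bulk simulator with known ground truth, chi-square
    tests of Mendelian segregation ratios, codon-level classification
    of SNP effects on gene models, and design of CAPS and dCAPS
    restriction-digestion genotyping markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    withr,
    stats,
    tools,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
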