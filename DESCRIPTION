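Package: growthscreen
Title: Growth Phenomics for Deletion-Library Fitness Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for plate-reader fitness screens of deletion libraries:
    extraction of growth rate and growth yield from OD600 time series,
    wild-type-referenced sigma scoring and phenotype classification across
    growth conditions, multiplicative-null epistasis scoring of double
    deletions, and positional enrichment of conserved upstream sequence
    elements (hypergeometric tests and a windowed k-mer over-representation
    scan). Includes seeded generators for synthetic plates, library truth
    tables and upstream flanking sequences with planted effects, so the whole
    pipeline can be exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
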