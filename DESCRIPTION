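Package: estssr
Title: Mining and Characterization of Simple Sequence Repeats in EST Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico pipeline for discovering perfect simple sequence
    repeats (SSRs, microsatellites) in expressed sequence tag (EST)
    collections and turning them into candidate PCR markers. Trims terminal
    poly-A/poly-T tracts, detects maximal perfect tandem repeats of period
    2-6 with a configurable minimum repeat number, removes redundant
    (identical or contained) sequences, computes catalogue statistics
    (SSR frequency, density, motif-class distributions, repeat-length
    histogram), and designs SSR-flanking primer pairs under PRIMER3-style
    constraints with nearest-neighbor melting temperatures. A seeded
    synthetic-EST generator with exhaustive ground truth makes every stage
    testable without external downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
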