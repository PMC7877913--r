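Package: selsignal
Title: Per-Gene Selection Signals in Somatic Mutation Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects per-gene signals of positive and negative (purifying)
    selection in coding somatic-mutation catalogues. Classifies every
    single-base substitution of the 61 sense codons as silent, missense or
    nonsense, computes expected category fractions for a transcript's codon
    composition under a six-class mutational-signature substitution profile,
    and derives per-transcript observed fractions (fS, fM, fN), ratio
    statistics (rSM, rNM, rNS, rSMN, rMSN, rNSM) and observed/expected
    "starred" metrics. Transcripts deviating from the central passenger
    cluster by more than a standard-deviation cutoff are called as
    candidates and assigned tumor-suppressor-like, oncogene-like or
    tumor-essential-like labels, with a recurrent-silent-hotspot guard
    against spurious purifying-selection calls. A seeded synthetic cohort
    generator with planted selection regimes makes every stage testable
    without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
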