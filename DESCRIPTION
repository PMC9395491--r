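Package: colloc
Title: Collocation Analysis of Animal Call Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects above-chance two-call combinations (bigrams) in animal
    vocal corpora using two collocation statistics from corpus linguistics:
    Multiple Distinctive Collocation Analysis (MDCA), a signed -log10 binomial
    tail probability over the cross-tabulated ordered-pair frequencies, and
    Mutual Information Collocation Analysis (MICA), the log2 ratio of observed
    over expected pair frequency under independent call-token frequencies.
    Includes bigram tabulation from pair lists or call sequences, significance
    banding, order-asymmetry (linearisation) reports, a synthetic planted-bigram
    corpus generator with a permutation null, delimited-text input/output, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
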