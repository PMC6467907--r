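Package: matrisk
Title: Maternal Risk-Management Classification of Breeder Investment Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies animal species into four natural-selection categories
    (predation, scarcity, weak, convergent) from breeder investments in
    offspring quantity (N) and relative offspring quality (S = m/M), using a
    replacement-fitness mortality model (P = 1 - w/N) and a bias-corrected
    rank-form Gini coefficient of brood inequality. Includes readers and
    writers for species-trait tables, quadrant plots with iso-mortality
    overlays, a seeded synthetic-species generator, and a Monte-Carlo harness
    for the conjecture that joint predation-and-scarcity mortality favors
    unequal broods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
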