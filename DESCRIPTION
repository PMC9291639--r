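Package: pobench
Title: Partial-Ordering Benchmark for Dose-Combination Finding Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes, by simulation under complete information, a
    nonparametric upper bound on the proportion of correct selections
    achievable by dual-agent dose-combination finding designs when the
    monotonic toxicity ordering of the combinations is unknown. Enumerates
    the feasible complete orderings (linear extensions) of the dose grid,
    weighs each ordering by a power-likelihood posterior given
    complete-information patient responses, and aggregates
    ordering-probability-weighted selections across simulated trials.
    Supports a single binary toxicity endpoint, multiple endpoints with
    discrete or continuous distributions (optionally correlated through a
    Gaussian copula), and Phase I/II toxicity-efficacy trade-off selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
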