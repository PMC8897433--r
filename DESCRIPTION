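Package: antbridge
Title: Stochastic Models and Analyses of Self-Assembled Army Ant Bridges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the dynamic control of self-assembled army ant
    bridges spanning a gap that repeatedly expands and contracts. Implements
    three discrete-time stochastic models of ants joining and leaving a bridge
    (fixed-probability baseline, leaving-delay variant, and a nonlinear
    accumulator driven by the deficit from an equilibrium packing density),
    the negative binomial and logistic fitting procedures that parameterize
    them from per-interval event data, a signed hysteresis-extent statistic
    for expansion versus contraction response curves, permutation resampling
    tests of whether bridge performance or tautness precedes joining and
    leaving events, and a synthetic trial generator that emulates the field
    data streams so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
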