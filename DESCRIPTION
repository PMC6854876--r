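Package: msinfl
Title: Two-State Markov-Switching Models for Annualized CPI Inflation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study regime changes in the annualized inflation of
    monthly consumer-price-index series, as used in evaluations of excise-tax
    pass-through to food and beverage prices. Transforms monthly index levels
    into year-over-year inflation, fits two-state Gaussian Markov-switching
    models by maximum likelihood (Hamilton filter, Kim smoother, multi-start
    optimization, robust standard errors), selects the autoregressive order and
    variance structure by information criteria, summarises regime persistence
    and expected durations, and simulates index and inflation series with a
    prescribed regime structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
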