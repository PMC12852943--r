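Package: revbandit
Title: Latent-State Bayesian Observer Models for Reversal Bandit Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing two-armed reversal bandit
    behaviour with grid-based Bayesian observer models. Generates correlated
    (two anti-phased latent states) and uncorrelated reward schedules with
    realistic trial timing, tracks joint beliefs over reward probability and
    reversal rate (or drift rate), derives trial-wise estimates (value,
    uncertainty, reversal probability, Kullback-Leibler update signals),
    simulates choice agents including perturbed policy presets, fits
    switch/stay policies by maximum likelihood with AIC model comparison,
    and provides per-session logistic switch regressions with two-stage
    group inference and consecutive-error switch-rate analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
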