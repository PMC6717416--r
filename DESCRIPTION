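Package: dermrisk
Title: Probabilistic Dermal Exposure Risk Assessment for Heavy Metals in Hair Dyes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for non-carcinogenic dermal risk
    assessment of heavy metals in cosmetic hair dyes. Handles left-censored
    (below detection limit) concentration data with configurable substitution
    and exclusion rules, fits and ranks parametric concentration
    distributions (lognormal, log-gamma, Weibull, Pareto, log-Laplace and
    generic alternates) by goodness of fit, propagates concentrations and
    exposure factors through the dermal dose equation by seeded Monte Carlo
    simulation, characterizes risk with hazard quotients and per-stratum
    hazard indices, and ranks input influence by Spearman rank correlation.
    Includes a synthetic-data generator that emulates an 8-brand by 4-color
    study design so every stage is testable without laboratory data.
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
    utils
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
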