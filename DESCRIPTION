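Package: stormlag
Title: Case-Crossover Distributed-Lag Models for Tropical Cyclone
    Exposure and Psychoactive Drug-Related Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating short-term associations between county-level
    tropical cyclone exposure and monthly cause-specific death rates using a
    Bayesian conditional quasi-Poisson, time-stratified case-crossover design
    with unconstrained distributed lags. Includes assembly of monthly
    exposure-day covariates from daily sustained-wind records, June-anchored
    linear population interpolation, ICD-9/ICD-10 classification of
    psychoactive drug-related deaths, piecewise natural-spline long-term
    trends, a second-order random-walk temperature adjustment, posterior
    post-processing (percent change per exposure day, additional deaths per
    million, subgroup contrasts, credible-interval sign classification),
    sensitivity drivers (lag windows, leave-one-state-out, acute versus
    chronic subcauses, period restriction), and a synthetic county-month
    panel generator with planted effects for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    splines,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
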