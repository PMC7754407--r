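Package: traumacost
Title: Health-Economic Markov Modelling of Policy-Related Childhood Trauma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of the health-sector and societal
    costs of border-control policies that expose migrant children to
    additional trauma. Provides a synthetic-cohort generator calibrated to
    a clinically referred trauma-exposed sample, severity stratification of
    functional-impairment item counts into quartile health states,
    proportional-odds (cumulative logit) estimation of the per-trauma odds
    of occupying a more severe state, a progression-only Markov cohort
    model with age-based mortality, prevalence-weighted annual cost accrual
    from health-sector and societal perspectives, cohort budget impact, and
    one-way deterministic, trauma-fraction sweep, and Monte Carlo
    probabilistic sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
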