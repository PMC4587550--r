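Package: kwaracea
Title: Cost-Effectiveness Modelling of Maternal Care Under the Kwara State
    Health Insurance Program
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic cohort model of maternal care in rural
    Nigeria comparing the current standard of care with care delivered under
    the Kwara State Health Insurance (KSHI) program. Propagates a cohort of
    pregnant women through antenatal care, delivery location and emergency
    obstetric care to four delivery complications (post-partum haemorrhage,
    sepsis, obstructed labour, hypertensive disorders) and their outcomes;
    accounts for provider-perspective costs (US$ 2012) and
    disability-adjusted life years; and computes incremental
    cost-effectiveness ratios with probabilistic (Monte Carlo), one-way
    (tornado) and scenario sensitivity analyses, cost-effectiveness
    acceptability curves, and a budget-impact projection of state-wide scale
    up. Includes an individual-level microsimulation of the same care
    pathway for validating the expectation-based engine and generating
    synthetic insurance-claims-like datasets.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
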