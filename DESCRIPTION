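Package: alcoburden
Title: Alcohol-Attributable Cancer Burden via Comparative Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative risk assessment of the
    alcohol-attributable burden of cancer, modelled on the Argentine 2018
    national estimates. Converts beverage-specific quantity-frequency survey
    responses into grams of ethanol per day, estimates survey-weighted
    prevalence of consumption levels, computes multi-level population
    attributable fractions (PAF) per cancer site and sex, turns ICD-10 coded
    vital-registration deaths, life tables and sequela-based YLD inputs into
    attributable deaths, YLLs, YLDs and DALYs, and evaluates counterfactual
    consumption-shift scenarios. Ships a synthetic-data generator with known
    ground truth emulating all five inputs (survey, death registry, life
    table, YLD table, relative-risk table) so the whole pipeline is testable
    without any external download, plus a micro-simulation oracle for the
    PAF estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
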