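Package: mddcourse
Title: Microsimulation of Educational Inequalities in Major Depressive
    Disorder Across the Life Course
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates age-banded incidence and remittance hazards of major
    depressive disorder (MDD) from two-wave panel data by sex and education,
    simulates individual life courses between ages 18 and 65 with a
    continuous-time two-state model under piecewise-constant hazards, and
    quantifies how counterfactually equalising modifiable factors (quality of
    social contacts, health literacy, smoking) across education groups would
    shrink educational inequalities in life-course prevalence, age of onset
    and duration of MDD. Includes a synthetic-cohort generator with known
    ground-truth dynamics, a mediation screen for modifiable factors,
    closed-form oracles for the two-state process, and life-course summary
    statistics with Monte Carlo uncertainty.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
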