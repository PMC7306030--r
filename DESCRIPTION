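Package: cipropk
Title: Population Pharmacokinetics and Target Attainment of Intravenous
    Ciprofloxacin in Critically Ill Patients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-compartment population pharmacokinetic modelling of
    intravenous ciprofloxacin in intensive-care patients: closed-form
    infusion kinetics, nonlinear mixed-effects estimation by a
    Laplace-with-interaction approximation (FOCE-I style), stepwise
    covariate search, model qualification by nonparametric bootstrap,
    visual predictive checks and normalized prediction distribution
    errors, and Monte Carlo probability-of-target-attainment simulation
    for fAUC/MIC and fCmax/MIC targets. Includes a synthetic-cohort
    generator emulating a sparse day-2 ICU sampling design so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr
Config/testthat/edition: 3
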