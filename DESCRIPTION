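Package: noacaf
Title: Decision-Analytic Markov Model of Anticoagulation in Subclinical
    Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Markov state-transition model estimating the net
    quality-adjusted-life benefit of initiating non-vitamin K antagonist oral
    anticoagulant (NOAC) therapy versus withholding it in patients with
    device-detected subclinical atrial fibrillation. Provides a patient-level
    microsimulation and an exact cohort-expectation solver over health states
    covering stroke and major-bleeding events with severity-dependent
    disability, a one-month post-bleed treatment pause, first-year post-event
    excess mortality, progression to clinical atrial fibrillation, and
    age-band utility accrual. Includes probabilistic sensitivity analysis with
    log-normal sampling of relative risks, one-command runners for scenario
    and sensitivity analyses, analytically solvable toy models for validation,
    and tidy result containers with broom-style tidiers and ggplot2 plots.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
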