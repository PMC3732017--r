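Package: surroval
Title: Surrogate Endpoint Validation for Time-to-Event Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level validation of candidate surrogate endpoints
    (disease-free survival, progression-free survival, locoregional
    control) for overall survival in multi-trial individual-patient
    time-to-event data. Individual-level rank correlation is estimated
    with a two-stage censored copula model (Clayton or Gumbel families,
    Kaplan-Meier margins); trial-level surrogacy is quantified by
    regression of treatment effects (log hazard ratios) weighted by
    trial size, with the surrogate threshold effect, fixed-horizon
    sensitivity analyses, and leave-one-trial-out prediction-interval
    validation. Includes a synthetic multi-trial data generator with
    known individual-level and trial-level association, so the whole
    pipeline is testable without access to patient data.
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
    pracma,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
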