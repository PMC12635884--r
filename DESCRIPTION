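Package: agescreen
Title: Age-Based Lung Cancer Screening Policy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling age-based low-dose CT lung cancer screening
    policy at desk scale: a calibrated synthetic patient cohort generator with
    survival endpoints, a screening-eligibility rule engine (USPSTF 2021 and
    expanded variants), Kaplan-Meier/Cox validation utilities, a stage-shift
    mortality model with number-needed-to-screen and parity solvers, a Monte
    Carlo cost-effectiveness engine (cost per life saved, ICER per QALY), a
    false-positive/procedure/complication harms cascade, and a BEIR VII-style
    lifetime attributable risk model for screening radiation exposure.
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
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
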