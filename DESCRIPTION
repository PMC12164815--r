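Package: dustrisk
Title: Probabilistic Human-Health Risk Assessment for Arsenic in Settled Dust
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-pathway (oral, dermal, inhalation) USEPA average-daily-dose,
    hazard-quotient and carcinogenic-risk calculations for populations exposed
    to metal-contaminated dust, with lognormal Monte Carlo propagation of
    concentration and body-weight uncertainty stratified by age group.
    Includes survey-design arithmetic for dust sampling campaigns under the
    Mexican NMX-AA-132 norm, limit-of-detection censoring policies,
    regulatory-threshold screening, a validated exposure-parameter registry
    with defaults for the Araro (Michoacan, Mexico) geothermal community
    study conditions, and a synthetic dust-survey generator with an XRF-style
    measurement-error model for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
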