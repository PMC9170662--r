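Package: cochleaCEA
Title: Cost-Utility Markov Model for Unilateral Cochlear Implants in Adults
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A Markov cohort cost-utility model comparing unilateral cochlear
    implants against hearing aids or no hearing aids in adults with severe to
    profound sensorineural hearing loss, from a health-system perspective with
    six-month cycles and a lifetime horizon. Provides distribution fitting for
    parameters reported as means with 95 percent confidence intervals,
    deterministic base-case evaluation, one-way (tornado) sensitivity analysis,
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, an individual-level microsimulation cross-check, and an internal
    validation battery. Ships a complete set of plain-text input tables
    (parameters, resource use, unit costs, utilities) plus synthetic stand-ins
    for the two inputs the model needs but which are not part of the published
    tables: an age-indexed all-cause mortality life table (Gompertz-Makeham)
    and an age-indexed population utility-norm curve.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
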