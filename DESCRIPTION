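Package: radfrac
Title: Macroscale Simulation of Tumor Response to Fractionated Radiotherapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete daily-update model of tumor volume response to external
    beam radiotherapy, coupling Gompertz regrowth of the active tumor,
    linear-quadratic cell survival, oxygenation-dependent radiosensitivity,
    vascular damage to the carrying capacity, and exponential clearance of
    necrotic volume. Builds fractionation calendars (constant-dose and ramped)
    at a fixed biologically effective dose (BED), ranks regimens per virtual
    patient by final active or total volume, computes the minimum BED needed to
    reach a prescribed regression, and fits the four free patient parameters to
    tumor-volume time series by seeded Monte Carlo random search. Ships a seven
    virtual-patient reference cohort for in silico fractionation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
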