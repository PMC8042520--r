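Package: crcscreen
Title: Cohort Decision Model of Colorectal Cancer Screening Disruption and FIT Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic cohort-level decision model of US colorectal
    cancer (CRC) screening over a three-year horizon, built to quantify the
    clinical consequences of pandemic-related colonoscopy disruption and of
    expanded fecal immunochemical test (FIT) outreach. The package evaluates
    scenario-specific modality uptake schedules against test performance,
    diagnostic adherence and stage-at-diagnosis inputs to produce counts of
    people screened, CRC cases by detection route, and early- versus
    late-stage diagnoses; compares scenarios; calibrates the
    symptomatic-presentation fraction in closed form; validates the
    deterministic engine against an individual-level Monte-Carlo
    microsimulator; and propagates parameter uncertainty through one-way
    (tornado) and probabilistic sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
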