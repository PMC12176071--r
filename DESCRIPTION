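Package: ehretl
Title: Quantifying the Impact of EHR Extraction and Processing Choices on
    Primary Care Research Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates raw general-practice electronic health record (EHR)
    extracts and processes them through two configurable
    extraction-transformation-loading (ETL) rule-sets of the kind used by
    Dutch primary-care research registries (enrollment-date versus
    capitation-based registration quarters, postal-code versus social
    security number pseudonymization, insurance-claims code filtering,
    8-day prescription deduplication, recorded episodes versus an
    episode-of-care construct built from ICPC-coded encounters). Links the
    two resulting research datasets on platform identifiers and compares
    them in three steps: demographics, paired per-patient utilization
    indicators of concordant patients, and diagnosis-group prevalence and
    utilization per 1000 patient-years with standardized differences. The
    goal is to make the consequences of individual ETL choices on research
    outcomes measurable without access to the original care data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
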