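Package: prepmonitor
Title: Quarterly Monitoring Indicators for HIV Pre-Exposure Prophylaxis Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the fourteen quarterly monitoring indicators used by a
    publicly funded province-wide HIV pre-exposure prophylaxis (PrEP) program
    from flat event tables (client roster, enrolment authorizations, pharmacy
    dispensations, laboratory results, adverse-drug-reaction reports, provider
    roster). Includes the active/inactive client-status algorithm built on
    prescription refill lapses and formal discontinuation notifications,
    testing-coverage window linkage between dispensations and laboratory
    tests, small-cell suppression for public reporting, and a synthetic-cohort
    simulator with independently bookkept ground truth so the whole pipeline
    is testable without access to confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    lubridate,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
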