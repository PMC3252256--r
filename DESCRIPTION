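Package: abxflow
Title: Ward Stock Accounting and Pharmacy Sales Agreement for Hospital Antibiotic Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hospital antimicrobial consumption surveillance in WHO
    ATC/DDD units. Computes weekly broad-spectrum antibiotic consumption per
    ward from two sources: shelf-count stock accounting corrected for
    deliveries, loans, discards and discharge take-aways, and pharmacy sales
    ledgers net of returns. Aggregates both series over registration
    intervals of one to four weeks, and quantifies their agreement with
    intraclass correlation coefficients from ANOVA variance components and
    Bland-Altman limits of agreement converted to interval-level DDD use
    ranges. Includes a discrete-event ward/pharmacy simulator (daily Poisson
    demand, reorder-point ordering, stock-flow events, missing count blocks)
    so the whole pipeline is testable without access to hospital data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
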