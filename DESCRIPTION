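Package: plancheckminer
Title: Data Mining of Radiotherapy Plan-Check Databases with SPC and
    Cohort DVH Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bulk ingestion and analysis of per-patient secondary
    dose-calculation plan-check records and dose-volume histogram (DVH)
    documents stored as JSON. Provides an open, versioned JSON dialect for
    plan-check and DVH files, a seeded stratified synthetic-cohort
    generator, flattening of approved checks into one analyzable record
    per plan-check, wildcard cohort filtering and grouped summary
    statistics, Shewhart-style statistical process control limits for
    mean-dose discrepancies with a hard gamma pass-rate floor, and cohort
    DVH meta-analysis (common-grid envelope curves and distributions of
    D(V), V(D) and maximum dose) for any searched structure. Includes a
    command-line driver for generation, ingestion, filtering, SPC and
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    dplyr,
    stats,
    utils,
    grDevices,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
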