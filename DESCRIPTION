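Package: inhalrisk
Title: Bioaccessibility- and Deposition-Adjusted Inhalation Risk
    Assessment for PM2.5 Metals
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A revised inhalation health-risk assessment pipeline for
    heavy metals bound to fine particulate matter (PM2.5). Computes
    simulated-lung-fluid bioaccessibility fractions (artificial lysosomal
    fluid and Gamble's solution), regional respiratory-tract deposition
    fractions per age/sex cohort, bioaccessibility- and
    deposition-adjusted average daily inhaled doses (ADD/LADD per the
    USEPA exposure framework), non-carcinogenic (HQ/HI) and carcinogenic
    (ILCR) risk characterization, and seeded Monte Carlo uncertainty
    propagation with cumulative-probability and exceedance summaries.
    Ships calibrated cohort registries and annual-mean concentration
    fixtures for a smelting-district study area, plus a synthetic
    filter-sample generator so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
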