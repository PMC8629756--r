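Package: ppvscreen
Title: Rare-Variant Collapsing and Penetrance-Based Screening of Population Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-based collapsing of qualifying rare coding and loss-of-function
    variants (and exon-level copy-number events) into per-sample burden
    indicators, phecode phenotype construction from dated ICD-9/ICD-10/ICD-10-CM
    diagnosis streams, covariate-adjusted Firth-penalized logistic association in
    two population cohorts, sample-size-weighted Z-score meta-analysis, and a
    dual-cohort positive-predictive-value (empirical penetrance) screen that
    flags gene-disease pairs as candidates for population genetic screening.
    Includes a seeded two-cohort synthetic-data generator with known carrier
    frequencies and penetrance for end-to-end validation.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
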