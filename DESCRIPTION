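Package: regharvest
Title: Harvest, Store and Harmonise Clinical Trial Registry Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling analysis-ready data sets from clinical trial
    registries. Translates high-level search parameters into the query grammars
    of ClinicalTrials.gov (CTGOV), the EU Clinical Trials Register (EUCTR), the
    EU Clinical Trials Information System (CTIS) and the ISRCTN registry; loads
    register-dialect records (XML or JSON) into a document-centric collection
    that preserves each register's own data model; discovers and extracts nested
    fields by dotted path into tidy tables; and computes twenty harmonised
    cross-register trial concepts (deduplication of multiply registered trials,
    start date, recruitment status, sample size, sponsor type, endpoint
    descriptions and more). A synthetic register-record generator renders
    ground-truth trials into all four dialects so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
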