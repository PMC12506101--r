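Package: bmirrda
Title: Harmonise Body Mass Index Records from Linked Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Retrieves, harmonises and evaluates the completeness of body mass
    index (BMI) records drawn from multiple linked electronic health record
    sources. Implements a staged pipeline: code-list based extraction of BMI
    components (values, heights, weights, categories, obesity diagnoses) from
    primary-care, hospital, maternity and child-measurement tables; unit
    standardisation and plausibility filtering; cohort construction with
    demographic exclusions and censoring; height-weight pairing and BMI
    derivation with adult cut-points and paediatric LMS z-score categories;
    two-stage same-day and over-time inconsistency cleaning; and resolution by
    a source hierarchy into a one-entry-per-person-per-day research-ready data
    asset. Ships coverage, preservation and source-overlap metrics and a
    synthetic linked-EHR generator with ground-truth labels and an independent
    reference implementation for differential testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
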