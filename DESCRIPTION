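Package: euctraudit
Title: Data Quality Audits for Multi-Country Clinical Trial Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to audit the completeness and internal consistency of
    multi-country clinical trial registry snapshots such as the EU Clinical
    Trials Register. Quantifies missing country protocols (inferred by
    comparing enrolment countries in tabular results against registered
    protocols), the quality of trial-status and global completion-date
    fields, and results availability, broken down by national regulator and
    over time. Includes a seeded synthetic-registry generator with a
    ground-truth defect ledger so every audit metric can be validated by
    parameter recovery.
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
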