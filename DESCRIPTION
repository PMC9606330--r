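Package: pvsignal
Title: Pharmacovigilance Signal Detection for Spontaneous Report Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for disproportionality analysis of
    FAERS-style spontaneous adverse event reports: ingestion of quarterly
    '$'-delimited case tables and a normalized CSV interchange format,
    two-step deduplication (last report version, then exact six-field
    duplicates), drug-name normalization against a synonym archive,
    mapping of MedDRA preferred terms into standardized query (SMQ)
    groupings, shrinkage-transformed reporting odds ratio and information
    component statistics with 95 percent interval bounds and a signal
    rule, time-to-onset summaries with exclusion accounting, outcome
    severity tabulation, and a synthetic report generator with planted
    ground truth so every stage is testable without a database download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
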