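Package: trackerforge
Title: Harmonize Multi-Site Diabetes Tracker Workbooks into Analysis-Ready Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An extract-clean-load toolkit for the monthly Excel tracker
    workbooks used by multi-country paediatric diabetes support programs.
    Workbooks are pseudonymized by replacing patient names with structured
    program identifiers via each tracker's "Patient List" roster, raw column
    headers are mapped onto a canonical schema through a YAML-driven synonym
    map, and cell values pass through a cleaning stage (multi-format date
    parsing, HbA1c inequality stripping, blood-pressure splitting,
    centimetre-to-metre height conversion, range and allowed-value checks)
    that substitutes conspicuous sentinel values instead of dropping records
    and logs every finding as a structured, coded validation event. Cleaned
    records are assembled into sorted patient and product tables serialized
    to Apache Parquet, and validation events aggregate into per-site,
    per-period data-quality audit reports. A seeded generator produces
    realistically messy synthetic tracker workbooks with a per-cell
    ground-truth manifest for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    jsonlite,
    readxl,
    rlang,
    tibble,
    utils,
    withr,
    yaml,
    zip
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
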