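Package: faersignal
Title: Curation and Disproportionality Signal Detection for FAERS/LAERS Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end curation pipeline for FDA spontaneous adverse-event
    reports. Reads the quarterly ASCII report tables in both the legacy (LAERS,
    isr/case keys) and current (FAERS, primaryid/caseid keys) dialects, merges
    them into unified case-version records, imputes single missing demographic
    values, de-duplicates case versions in two steps (latest-version selection,
    then demographic-key collapse), maps verbatim drug names to standard
    vocabulary concepts and MedDRA preferred terms to SNOMED-CT, enumerates
    drug-outcome pairs, and computes proportional reporting ratios (PRR) and
    reporting odds ratios (ROR) with 95 percent confidence intervals, writing
    the standard_* tab-delimited output tables. Includes a seeded synthetic
    corpus generator with independent ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
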