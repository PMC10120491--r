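Package: dmcreport
Title: Structured Safety Reports for Data Monitoring Committees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns CDISC ADaM-like clinical-trial safety tables (subject-level
    demographics, adverse events, laboratory measurements, exposure records)
    into a purposefully structured Data Monitoring Committee (DMC) report.
    Provides subject-level and exposure-adjusted adverse-event incidence, an
    adverse-event volcano display built on a two-sided Fisher exact test with
    Benjamini-Hochberg false-discovery-rate adjustment, laboratory
    normal-range flagging and CTCAE-style grading, box-whisker and
    abnormal-prevalence summaries over visits, spaghetti and shift displays,
    one-page patient profiles, and an assembler that emits a single
    continuously page-numbered report (PDF and hyperlinked HTML) with a
    machine-readable manifest. A seeded synthetic-trial generator with
    injectable safety imbalances makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    patchwork,
    ragg,
    readr,
    haven,
    yaml,
    jsonlite,
    stats,
    grid,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
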