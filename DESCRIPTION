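Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection in spontaneous
    reporting system extracts (FAERS/OpenVigil-style delimited tables): report
    ingestion with case-level deduplication and suspect-role filtering,
    descriptive epidemiology of the curated case series (country, age, sex,
    outcome and preferred-term distributions, reporting rates, System Organ
    Class aggregation), per-term 2x2 contingency tables with proportional
    reporting ratio (PRR), reporting odds ratio (ROR) with Woolf confidence
    intervals and chi-square statistics, Evans-criteria signal classification,
    and bubble-plot coordinates. Includes a seeded synthetic spontaneous-report
    generator with injected drug-event associations of known odds ratio, so
    every stage of the pipeline can be validated without access to a real
    reporting database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
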