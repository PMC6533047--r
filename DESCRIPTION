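Package: symptomlag
Title: Temporal Screening of Symptom Queries Preceding Treatment-Information Seeking in Search Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing timestamped web-search logs to find medical
    symptoms whose querying rises before a user first seeks information on
    12-step addiction programs (Alcoholics Anonymous / Narcotics Anonymous).
    Provides readers and writers for tab-separated query logs, a synonym
    lexicon matcher that maps free-text queries to canonical medical symptoms,
    click-based discovery of treatment-seeking seed queries, cohort assignment
    (target treatment seekers versus comparison users), a between-group
    probability-ratio screen, a time-lagged within-person 2x2 chi-square
    screen over three pre-index windows with Bonferroni correction, a
    persistence taxonomy of significant symptoms, and a seeded synthetic-log
    generator with planted effects for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
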