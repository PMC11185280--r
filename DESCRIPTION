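Package: alertevents
Title: Automated Event Analysis of Persistent and Absent Medication Alerts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates acceptance of passive, noninterruptive medication
    alerts issued by computerized physician order entry (CPOE) systems with
    an integrated clinical decision support system (CDSS). Prescription and
    alert display logs are rasterized into midnight-anchored 24-hour
    intervals; follow-up prescriptions are chained into continuous
    prescription units; every alert is classified as persistent or absent
    (or excluded by one of three rules), and its display duration (DDoA) is
    computed. Includes per-alert-type summaries with pairwise chi-square
    comparisons of absence rates, discrete time-to-absence curves, and a
    seeded synthetic CPOE event-log generator with ground-truth labels for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
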