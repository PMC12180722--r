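Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance analysis of spontaneous
    adverse-event reports distributed as FAERS-style quarterly ASCII packets.
    Implements case deduplication by CASEID/FDA_DT/PRIMARYID with deleted-case
    catalogs, drug-event two-by-two contingency construction at the MedDRA
    preferred-term or system-organ-class level, four disproportionality
    algorithms (reporting odds ratio, proportional reporting ratio with Yates
    chi-square, the BCPNN information component, and the multi-item gamma
    Poisson shrinker EBGM) with joint signal criteria, descriptive cohort
    summaries, and time-to-onset analysis with two-parameter Weibull maximum
    likelihood and failure-mode classification. Includes a synthetic FAERS-like
    data generator with a ground-truth ledger so every stage is testable
    without downloading the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse
Config/testthat/edition: 3
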