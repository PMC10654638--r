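Package: pvsignal
Title: Pharmacovigilance Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("FAERS", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Disproportionality analysis for spontaneous adverse-event
    reporting databases in the style of the FDA Adverse Event Reporting
    System (FAERS). Provides a report store with drug-name normalization,
    case-level deduplication and primary-suspect filtering; a statistics
    engine computing reporting odds ratios (ROR) with Wald confidence
    intervals, proportional reporting ratios (PRR) and Yates-corrected
    chi-squared with standard signal criteria; pairwise comparison of
    signal strength between two drugs; off-label indication mining with
    within-indication adverse-event profiles; demographic, temporal and
    outcome descriptives; and a synthetic report generator with planted
    drug-event odds ratios so the whole pipeline is testable without any
    database download. A reconstruction oracle back-solves 2x2 tables
    from published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
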