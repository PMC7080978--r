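Package: vigisignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("VigiSignal", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pharmacovigilance signal-detection pipeline for collections of
    individual case safety reports (ICSRs): validated readers and writers for
    JSON-lines and flat-CSV report collections, route/age/period cohort
    filters, preferred-term to standardized-query (SMQ-style) event mapping,
    2x2 contingency construction against an all-other-reports comparator,
    proportional reporting ratio (PRR), reporting odds ratio (ROR) and
    Bayesian information component (IC/IC025) estimation with interval bounds
    and the three-case rule, multiplicative completeness scoring of case
    documentation, WHO-UMC style causality classification, time-to-onset
    summaries, and a seeded synthetic spontaneous-report generator with
    planted drug-event reporting-rate ratios for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
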