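Package: rarseek
Title: Recurrently Altered Region Discovery and Prognostic Marker Mining
    for Array-CGH Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for somatic copy-number analysis of array-CGH
    log2 tumor/reference ratio profiles. Segments each sample's
    probe-ordered ratios with a rank-statistic recursive splitting
    procedure, calls gains, losses, high-level amplifications and
    homozygous deletions with fixed log2 thresholds, delineates
    recurrently altered regions (RARs) across a cohort against a
    circular-shift permutation null, classifies RARs as earlier or
    later events by tumor stage, mines predictive association rules
    (CPAR with Laplace accuracy) linking RAR markers to survival
    status, and evaluates single and combined markers with
    Kaplan-Meier, log-rank and Cox proportional-hazards analysis.
    Includes a synthetic-cohort generator with implanted alterations,
    proportional-hazards survival and qPCR Ct simulation, so the whole
    pipeline is testable without patient data, and a delta-delta-Ct
    module for genomic qPCR replication cohorts.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
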