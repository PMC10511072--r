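Package: ctriaudit
Title: Audit of Recruitment and Reporting Compliance in Clinical-Trial Registry Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to audit snapshots of the Clinical Trials Registry-India
    (CTRI). Classifies phase 2/3 interventional trial records as domestic,
    multinational or ambiguous using three pairs of registry fields with a
    unanimity requirement; computes planned and actual fractions of
    recruitment from India and flags over-recruitment at a configurable
    cutoff with a sensitivity sweep; bins the actual-to-planned recruitment
    ratio; and detects records whose completion status ought to have been
    updated, using a duration-dependent grace-margin rule and a six-month
    filing allowance. Includes readers and writers for SQLite and CSV
    registry snapshots with faithful sentinel handling, and a seeded
    synthetic-registry generator with ground-truth labels and injectable
    error modes for end-to-end validation without access to the live
    registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
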