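Package: harmsynth
Title: Auditing Adverse-Event Synthesis in Rare-Event Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing how adverse-event evidence is synthesised in
    meta-analyses of clinical trials, motivated by conflicting conclusions
    about serious adverse events of intraarticular hyaluronic acid for knee
    osteoarthritis. Provides per-study effect measures for rare binary harms
    (risk ratios with explicit zero-cell rules) and for continuous function
    outcomes (Hedges-corrected standardized mean differences); pooling by
    inverse-variance fixed effect, DerSimonian-Laird random effects,
    Mantel-Haenszel, and exact conditional inference on the common odds
    ratio for sparse stratified 2x2 tables; two-axis (severity x locality)
    classification of reported adverse events under competing schemes; a
    scenario-ladder sensitivity engine covering study exclusions, subgroup
    restrictions and named event deltas; and bounded integer inversion that
    recovers withheld per-study event counts from a published pooled
    estimate. A synthetic-trial generator makes every stage testable
    without access to the original trial reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
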