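Package: qhtscreen
Title: Quantitative High-Throughput Screening Analysis for Nuclear
    Receptor Antagonist Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cell-based quantitative high-throughput
    screens (qHTS) run in 1536-well plates against a luciferase reporter
    readout, with a fluorescent cell-viability counter-screen.  Provides
    plate normalization to vehicle and positive controls, DMSO-plate
    background pattern correction, plate quality metrics (CV, S/B, Z'
    factor), four-parameter Hill concentration-response fitting, qHTS
    curve classification and curve-rank scoring, activity calling with
    cytotoxicity triage, self-organizing-map clustering of compound
    fingerprints with Fisher's exact enrichment of active clusters,
    pharmacological IC50-shift confirmation analysis, and delta-delta-Ct
    qPCR fold-change statistics with Dunnett's many-to-one comparisons.
    A synthetic screen generator with planted antagonists, cytotoxic
    compounds and spatial plate artifacts supports end-to-end validation
    of every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    mvtnorm,
    stats,
    utils
Suggests:
    jsonlite,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
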