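Package: diaflux
Title: Pathway Impact and Transcription-Factor Activation-State Inference
    from Differential-Expression Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream functional analysis of bulk RNA-seq differential
    expression results. Selects differentially expressed genes at an FDR
    cutoff, scores pathways and transcription-factor regulons with a
    dynamic-impact style statistic (impact) and its signed counterpart
    (flux), tests regulons for over-representation with the exact
    hypergeometric test under Benjamini-Hochberg FDR control, calls each
    significant regulon Activated or Inhibited from its flux sign, expands
    multi-level pathway neighbourhoods from seed pathways, and assembles a
    tri-partite transcription factor - gene - pathway network. A seeded
    synthetic-data generator produces differential-expression tables with
    planted activated and inhibited gene sets so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
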