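Package: gwgs
Title: Cross-Study Rank Integration of Microarray Data with GWRS/GWGS Scoring
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrated meta-analysis of multiple two-group expression
    studies by rank aggregation. Each study is summarised by per-gene
    fold-change ranks over the common gene universe; ranks are converted
    to genome-wide relative significance (GWRS) scores and combined across
    studies into a weighted genome-wide global significance (GWGS) score,
    from which a top-K gene signature is selected. Downstream stages test
    the signature for gene-set enrichment with Fisher-exact and EASE
    scoring, and build the signature-induced protein-interaction
    subnetwork with degree-based hub calling. A synthetic-data module
    generates multi-study expression matrices, gene-set collections and
    interaction networks with planted ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
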