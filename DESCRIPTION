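Package: sigrank
Title: Gene-Set Signature Scoring and Rank-Based Selection of Cell-Line Models
Version: 0.1.0
Authors@R: person("sigrank", "developers", role = c("aut", "cre"),
    email = "sigrank@example.org")
Description: Ranks expression profiles (cell lines, microdissected tissues)
    by gene-set signature strength: quantile normalization of summarized
    log2 matrices, probe-to-gene collapse by maximal standard deviation,
    gene-wise zero-centering, set-average scoring and rank tables. Includes
    gene set enrichment analysis with a gene-set-resampling null,
    mining of drug-response (-log GI50) matrices for response-associated
    gene signatures, Kaplan-Meier / log-rank survival stratification by
    signature score, and a synthetic-data generator with planted ground
    truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    limma,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
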