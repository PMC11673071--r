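Package: npvuln
Title: Neuropeptide Co-Expression Vulnerability Analysis for Brain Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores single cells by neuropeptide (NP) co-expression, stratifies
    neurons into low/medium/high NP-producing groups, and tests for
    condition-dependent depletion of high-NP neurons; runs Wilcoxon rank-sum
    differential expression with Benjamini-Hochberg FDR control and per-gene
    regression on NP co-expression count; performs hypergeometric gene-set
    overlap tests; quantifies age-associated decline of cumulative
    AD-associated neuropeptide (ADNP) expression in bulk brain RNA-seq with
    covariate-adjusted partial Spearman correlation; and estimates the
    regional abundance of high-ADNP neuronal clusters from cluster annotation
    tables. Includes seeded synthetic-data generators that emulate the
    statistical structure of the public datasets these analyses target, so
    every stage is testable end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
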