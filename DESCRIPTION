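Package: pepgrow
Title: Competitive Growth Analysis of Barcoded Random-Peptide Expression Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying fitness effects of random open reading frames
    and heterologously expressed de novo genes in cultured cells. Models a
    library of 150-nt random inserts expressed as 58-residue tagged peptides,
    including the geometric null for stop-truncated peptide lengths and
    per-sequence composition features. Simulates multi-replicate serial-passage
    competitive growth with per-clone fitness and amplicon sequencing with
    substitution errors; counts barcode reads against a reference built by
    abundance-ranked Hamming collapse; tests clone abundance changes between
    timepoints with a negative-binomial Wald test (median-of-ratios
    normalization, Benjamini-Hochberg adjustment) and classifies clones as
    increasing, decreasing or unchanged. Includes group-level sequence-feature
    comparisons (two-sample Kolmogorov-Smirnov tests, boxplot statistics,
    aggregation-propensity flags) and meta-analyses of per-gene summary tables
    (tie-aware Spearman correlation, foldability classification from intrinsic
    disorder scores, differential-expression filtering, and cross-experiment
    recurrence of top-responding genes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    S4Vectors,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
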