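Package: dermalscore
Title: Aging-Related Composition and Stemness Analysis of Dermal Fibroblast Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing age-related changes in human
    dermal fibroblast populations from droplet single-cell RNA-seq unique-count
    data. Provides cell-level quality-control filtering (expressed-gene and
    mitochondrial-fraction thresholds), per-cell log count normalisation,
    one-vs-rest Wilcoxon rank-sum marker statistics, gene-signature scoring and
    dot-plot summaries, a hypergeometric over-representation test, a
    reference-based per-cell stemness score built from a stem-versus-fibroblast
    differential-expression table, and young-versus-old cluster-composition
    analysis via Fisher's exact odds ratios with Woolf confidence intervals and
    per-donor fraction t-tests. A negative-binomial synthetic-cohort generator
    with planted population programs, composition shifts and a planted
    differential-expression reference makes every stage testable end-to-end
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
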