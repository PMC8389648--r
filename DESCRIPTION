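Package: gsreg
Title: Gene Set Regularity Analysis of Expression Functionomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rank-conservation gene set analysis for case/control expression
    cohorts. Builds per-gene-set pairwise expression-ordering templates from
    control samples, scores every sample with a gene set regularity (GSR)
    index (the fraction of within-set gene pairs whose ordering matches the
    control majority), and assembles the per-sample vector of indices over a
    GO gene set collection (the functionome). Downstream tools screen gene
    sets for dysregulation with Mann-Whitney tests and Benjamini-Hochberg
    correction, rank significant terms by a cluster weight index, classify
    profiles with cross-validated support vector machines, intersect
    top-ranked pathway lists across disease groups, count gene annotation
    frequencies over selected terms, and compute immunohistochemistry
    composite scores. A synthetic two-group cohort generator with known
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    kernlab,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
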