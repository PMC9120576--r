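Package: fbnclass
Title: Functional Brain Network Estimation, Graph Metrics, and
    Multi-Kernel SVM Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates Pearson-correlation functional brain networks from
    regional time series, binarizes them over a proportional sparsity grid,
    computes global and nodal graph-theory measurements normalized against
    degree-preserving rewired null networks, and classifies two-group
    cohorts with a multi-kernel support vector machine combining connection
    weights with global and nodal metric features under leave-one-out
    cross-validation. Includes fold-wise t-test feature selection with
    consensus-connection extraction, ROC/AUC with the DeLong test for
    correlated curves, group-level hub and metric comparisons, and a
    synthetic two-group cohort generator with planted connectivity
    differences for end-to-end testing without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
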