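Package: gbnea
Title: Gene Behaviors-Based Network Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether functional gene sets (e.g. KEGG pathways) are
    over-represented among the genes whose regulatory behavior differs most
    between two phenotype-specific directed gene networks. Networks are
    estimated per phenotype by sparse per-target elastic-net regression with
    BIC model selection; per-gene phenotype-distinction statistics combine
    regulatory effects (edge weight times mean expression), edge sign and
    magnitude, and a Jaccard distance between node neighborhoods; gene sets
    are scored with a weighted Kolmogorov-Smirnov running-sum enrichment
    statistic whose significance is assessed by phenotype-label permutation
    with Benjamini-Hochberg correction across pathways. Includes a synthetic
    two-phenotype data generator with planted, pathway-localized network
    differences for benchmarking, plus readers and writers for expression
    matrices, phenotype tables, GMT gene sets and network edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    parallel
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
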