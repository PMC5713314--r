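Package: funcgsr
Title: Function-Based Transcriptome Analysis with Gene Set Regularity Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-sample regularity of gene set expression orderings
    (the gene set regularity, GSR, index; a rank-conservation statistic in the
    DIRAC family) and converts expression matrices into a samples-by-functions
    "functionome". Downstream stages extract deregulated functions
    (Mann-Whitney tests with Benjamini-Hochberg correction), evaluate
    disease-pattern informativeness by cross-validated linear support vector
    machines and hierarchical clustering, uncover factor structure among
    deregulated terms (parallel analysis, principal-axis factoring, promax
    rotation) with Gene Ontology tree summarisation, rank progressively
    deregulated functions along a disease transition, and reconstruct a
    mutual-information function network (k-nearest-neighbour entropy
    estimation with ARACNE pruning). A synthetic-cohort generator emulates
    tissue-matched case/control designs so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    kernlab,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
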