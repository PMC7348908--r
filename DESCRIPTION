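Package: cpi
Title: Comparative Pathway Integration Across Transcriptomic Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Meta-analytic pathway enrichment across multiple transcriptomic
    studies. Per-study over-representation (hypergeometric) or
    Kolmogorov-Smirnov enrichment p-values are combined with the adaptively
    weighted Fisher method, which attaches a 0/1 study weight vector to each
    pathway and so separates consensually from differentially enriched
    pathways. Significant pathways are de-duplicated by tight clustering on
    Cohen kappa gene-overlap similarity (consensus clustering to choose the
    number of clusters, iterative silhouette-based removal into a scattered
    set), and each pathway cluster is annotated with keywords by a
    length-penalized permutation test on noun phrases extracted from pathway
    names and descriptions. Includes synthetic-data generators emulating the
    assumed multi-study design for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    yaml
Config/testthat/edition: 3
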