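Package: coexhub
Title: Weighted Gene Coexpression Networks and Hub-Gene Candidates for
    Quantitative Traits
Version: 0.1.0
Authors@R:
    person("coexhub", "maintainers", email = "maintainers@coexhub.dev",
           role = c("aut", "cre"))
Description: Builds unweighted (hard-threshold) and weighted (soft power)
    gene coexpression networks from log2 expression matrices, computes the
    topological overlap matrix and detects colored gene modules by
    average-linkage clustering, profiles network topology (connectivity,
    betweenness, closeness, clustering coefficients, scale-free and
    exponentially truncated power-law fits), selects hub and
    high-betweenness candidate genes, tests gene-set over-representation
    with Fisher's exact test, and validates candidates against a
    quantitative trait (group statistics, fold change, covariate-adjusted
    regression, PCA). Includes a synthetic-data generator with planted
    correlated modules, hub genes and a trait-linked latent factor so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
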