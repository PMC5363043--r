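Package: miccnet
Title: Multi-Network Consensus Clustering of Co-Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative multi-dataset analysis of gene expression via
    mutual-information consensus clustering (MICC). Detects signed weighted
    co-expression modules per dataset, links modules across datasets through
    an information-theoretic overlap score to form a module overlap network,
    finds hierarchical communities in that network, derives tissue consensus
    gene sets from disease-enriched communities, and interrogates
    tissue-specific weighted functional networks (hubs, bridges, functional
    modules, differential network analysis between tissues). Includes
    single-sample gene-set z-score summaries, a permutation-based
    differential-expression statistic, and a synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
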