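Package: modulepivot
Title: Co-Expression Dysfunction Modules, Pivot Regulators and Drug-Reversal
    Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for dysfunction-module analysis of
    case/control/treatment expression studies: weighted co-expression module
    detection (soft-thresholded adjacency, topological overlap, average-linkage
    clustering with a static height cut and size filters), flat hypergeometric
    gene-set over-representation per module with Benjamini-Hochberg correction,
    hypergeometric pivot analysis of ncRNA and transcription-factor regulators
    against interaction-table backgrounds, directional drug-target reversal
    calling from differential expression (inhibited and promoted target sets),
    and degree-based hub ranking with connected-component clusters on
    score-filtered protein-protein interaction networks. Ships a synthetic-data
    generator that plants correlated gene blocks, directional disease effects
    partially reversed by simulated treatments, module-specific regulators and
    network hubs, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    limma,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
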