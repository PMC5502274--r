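Package: berrynet
Title: Co-Response Networks for Grape Berry Water-Deficit Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated network analysis of fruit transcriptome and metabolome
    responses to water deficit. Computes stage-wise log2(WD/CT) response
    profiles for genes and metabolites, detects weighted co-expression
    modules (topological overlap, eigengenes, module merging) in both
    co-response and developmental modes, assesses correlation significance
    with permutation-based empirical p-values, tests promoter enrichment of
    degenerate IUPAC cis-regulatory elements per module (hypergeometric test
    with FDR control), links modules to co-responding metabolites, and builds
    gene-metabolite subnetworks exportable to Cytoscape (SIF/GraphML). A
    synthetic-data generator with planted ground truth reproduces the
    statistical structure of a two-treatment, multi-stage, replicated field
    design so the whole pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    xml2,
    yaml,
    jsonlite,
    withr,
    Biostrings,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
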