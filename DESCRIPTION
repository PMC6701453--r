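Package: coexnet
Title: Cross-Species Weighted Gene Coexpression Networks and Hub Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Weighted gene coexpression network analysis for chronic-exposure
    transcriptome studies: probeset filtering, soft-thresholded adjacency and
    topological overlap, dynamic tree-cut module detection, module eigengenes
    and membership, eigengene-phenotype correlation with treated-only
    phenotype conventions, empirical-Bayes moderated differential expression,
    hypergeometric gene-set overlap, permutation module validation, a
    composite hub-ranking score (ERHS), two-species consensus (meta-) module
    analysis over a homolog map, and control-versus-treated differential
    connectivity. Includes a synthetic-data generator with planted module,
    hub, phenotype and treatment structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust,
    igraph,
    yaml
Config/testthat/edition: 3
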