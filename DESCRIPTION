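Package: methylGEMM
Title: Cross-Species DNA Methylation and Expression Analysis of
    Rhabdomyosarcoma Mouse Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for Infinium-style methylation array data from
    genetically engineered mouse models (GEMMs) of rhabdomyosarcoma and their
    comparison with human tumours. Provides probe-level promoter/gene-body
    annotation against transcript models, subset-quantile within-array (SWAN
    style) normalization of two-design-type intensities, selection of the most
    variable probes, unsupervised hierarchical clustering with nested subset
    cuts and t-SNE embedding, exact two-by-two association statistics (Fisher
    exact test, Cohen's kappa), differential methylation and expression
    calling with direction-stratified gene-region integration, cross-species
    conserved-gene identification via syntenic probe and homolog maps, and
    hypergeometric gene-set enrichment. Includes a seeded synthetic-cohort
    generator with planted ground truth so that every stage of the pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
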