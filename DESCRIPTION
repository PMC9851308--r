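Package: lipidnet
Title: Lipid Species Networks and Enzymatic Dysregulation Enrichment for
    Lipidomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds dataset-specific lipid species metabolic networks from
    curated lipid-class reaction templates and shorthand lipid nomenclature
    (sum and molecular species), infers enzymatic dysregulation between two
    sample groups through substrate-product reaction scoring on a reaction
    (hyper)network combined with a simulated-annealing local search and an
    empirical p-value, and characterises lipidome composition shifts with
    moiety (substructure) features and per-sample reaction ratios. Ships a
    synthetic two-group lipidomics generator with a planted multispecific
    acyl-transferase dysregulation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    glmnet,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'acyl.R'
    'AllGenerics.R'
    'AllClasses.R'
    'registry.R'
    'parse.R'
    'enumerate.R'
    'reactions.R'
    'experiment.R'
    'network.R'
    'reaction-network.R'
    'scoring.R'
    'search.R'
    'stats.R'
    'simulate.R'
    'io.R'
    'cli.R'
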