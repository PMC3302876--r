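Package: spip
Title: Integrated Evidence Scoring of Proteome Members of a Molecular Machine
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores every protein in a proteome for membership in a
    molecular machine (the mitotic spindle) by combining orthogonal
    evidence channels -- literature co-citation specificity, domain-fusion
    (Rosetta-stone) association, domain over-representation,
    homology-inherited protein-protein interactions, gene co-expression,
    Resnik semantic similarity over an annotation ontology, and a
    feature-based neural-network classifier -- into a single ranked list
    with a unified p-value via two-stage Fisher integration. Includes
    ranked-list benchmarking (ROC/PR, windowed fold enrichment, runs and
    permutation tests), mutual-information independence diagnostics,
    hidden-hub mining of the predicted interaction network, and a seeded
    synthetic-benchmark generator with a planted positive module.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    nnet,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
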