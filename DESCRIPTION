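Package: generank
Title: Hybrid Gene Selection with Fisher Filtering, GO-Aware Redundancy
    Reduction and SVM-RFE
Version: 0.1.0
Authors@R:
    person("generank", "developers", email = "generank@example.org",
           role = c("aut", "cre"))
Description: Selects candidate marker genes from two-class expression
    matrices with a three-stage pipeline: univariate Fisher-criterion
    filtering, greedy redundancy reduction driven by a combination of
    Pearson expression similarity and Lin information-content semantic
    similarity over a Gene Ontology DAG, and recursive feature
    elimination with a linear support vector machine.  Evaluation uses
    external cross-validation in which the entire selection pipeline is
    re-run inside every training fold, avoiding selection bias.  Includes
    a synthetic-data generator (planted differential genes, planted
    redundant gene groups, and a matching toy ontology) so the whole
    pipeline is testable without external downloads, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
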