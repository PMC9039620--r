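Package: pagsuite
Title: Gene-Set Enrichment, Term Reconciliation, Co-Membership Networks
    and Literature Validation for PAG Collections
Version: 0.1.0
Authors@R:
    person("PAG", "Suite Developers", email = "pagsuite@example.org",
           role = c("aut", "cre"))
Description: Offline toolkit for over-representation analysis of candidate
    gene lists against collections of PAGs (pathways, annotated gene lists
    and gene signatures) with a rank-aware p-value adjustment; reconciliation
    of enrichment terms reported by different tools via optimal string
    alignment (OSA) similarity and consensus (Venn) partitioning; m-type
    (co-membership) PAG-to-PAG network construction with Louvain community
    detection and per-community keyword extraction; and a literature
    co-citation validation framework (PubMed score, odds ratio, ROC/AUC
    against a ground-truth rule, top-versus-bottom t-test curve, precision
    at cutoffs). Includes a seeded synthetic-fixture generator so every
    analysis is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
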