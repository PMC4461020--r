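Package: mirdnet
Title: miRNA-Disease Association Networks: Matching-Based Disease
    Prioritization and Motif Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing weighted bipartite miRNA-disease
    association networks, where edge weights count the publications
    supporting each association. Given a query set of miRNAs, diseases
    are prioritized by an exact maximum-weight bipartite matching
    combined with a cumulative-impact ranking and a merge rule that
    recovers strong associations the matching's vertex-disjointness
    constraint would otherwise discard. A second, structural route
    ranks diseases by their participation in connected three- and
    four-node subgraphs (paths, stars and squares), with significance
    assessed against a degree-preserving edge-swap null ensemble.
    Also included: the disease-disease one-mode projection, topology
    summaries (density, degree distributions, descriptive power-law
    fits), shortest-path queries, CSV readers/writers, GNU MathProg
    model export, synthetic scale-free bipartite network generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
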