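Package: hubnet
Title: Hub Gene Prioritization on Protein Interaction Networks with
    Robustness Validation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Topology-driven prioritization of candidate disease genes on
    protein-protein interaction networks. Builds confidence-filtered
    interaction graphs, computes node degree and normalized betweenness
    centrality, selects hub genes by a dual strict cutoff, extracts the
    hub backbone subnetwork, and validates hub stability with a
    leave-1-to-4-node test-network design and an accuracy statistic.
    Also ranks transcription factors in a bipartite promoter-evidence
    regulatory network, analyses qPCR data with the comparative Ct
    (2^-ddCt) method, and ships seeded generators for scale-free networks
    with planted hubs, TF binding-evidence tables and Ct tables so the
    whole pipeline runs on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, GeneExpression,
    qPCR, Network
RoxygenNote: 7.3.3
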