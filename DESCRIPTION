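Package: netpharm
Title: Network Pharmacology Screening of Herbal Compound-Target Networks
Version: 0.1.0
Authors@R: person("netpharm", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A reproducible network-pharmacology workflow for multi-herb
    remedies: six-criterion ADME/drug-likeness screening of compound tables
    (molecular weight, AlogP, hydrogen-bond donors/acceptors, oral
    bioavailability, Tanimoto drug-likeness), assembly of herb-compound-target
    bipartite networks, intersection of drug targets with disease gene lists,
    iterative degree/closeness/betweenness screening of confidence-scored
    protein-protein interaction networks to extract core targets, and
    hypergeometric gene-set over-representation analysis with
    Benjamini-Hochberg correction. Ships the compound, target and disease-gene
    tables of a published eight-herb decoction study as plain-text fixtures,
    plus seeded synthetic generators for every input so the whole pipeline is
    testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
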