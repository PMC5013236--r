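Package: netarch
Title: Topological Characterization and Classification of Signalling Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative topological analysis of curated
    signalling networks, such as literature-derived protein interaction
    maps of actin dynamics. Reads edge lists, Cytoscape SIF files and
    curated interaction tables; cleans, merges and filters networks;
    computes the standard topological parameters (connected components,
    clustering coefficients, shortest-path statistics, diameter,
    characteristic path length, mean neighbourhood size) from first
    principles; fits power laws to degree distributions and to the
    degree versus clustering relation by least squares on logarithmized
    data; identifies hubs by the mean-plus-one-standard-deviation degree
    rule; classifies networks as Barabasi-Albert-like scale-free or
    hierarchical; and generates seeded synthetic reference networks
    (preferential attachment, Erdos-Renyi, Ravasz-style hierarchical)
    spanning those structural regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
biocViews: Network, GraphAndNetwork, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
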