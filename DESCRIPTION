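Package: silocate
Title: Multi-Source Epidemic Source Localization on Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates the origin nodes of a spreading process (rumor,
    epidemic) from a single infection snapshot of a contact network.
    Implements a discrete-time susceptible-infected (SI) simulator with
    per-edge transmission probabilities, an entropy-based locator (SLBNE)
    that scores each infected node by its neighborhood entropy and reports
    the local maxima as the core convex set, and a cluster-based locator
    (SLBIC) that partitions the infected subgraph around the core nodes
    and adds the most cohesive node of each infection cluster. Includes
    the standard evaluation metrics (F-score, average error distance,
    source-count accuracy), Erdos-Renyi and Barabasi-Albert generators,
    and a reproducible benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
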