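Package: pidscales
Title: Partial Information Decomposition of Boolean Network Dynamics Across Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how information is converted between redundant and
    synergistic forms when a discrete dynamical system is modelled at
    different scales. Boolean networks and row-stochastic transition
    probability matrices are analysed through the temporal mutual
    information between joint past and joint future states, decomposed into
    partial-information atoms on the Williams-Beer redundancy lattice, and
    summarised as a partial-information spectrum with synergy and redundancy
    biases. Includes logic-gate micro/macro circuit fixtures, mutual-
    information-preserving equivalence-class expansions of transition
    matrices, random-matrix ensemble experiments, and the effective-
    information determinism/degeneracy decomposition used in studies of
    causal emergence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
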