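Package: coalnet
Title: Coalitional Better-Response Dynamics for Cooperation on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of the evolution of cooperation when
    connected groups of individuals on a fixed interaction graph jointly
    revise their prisoner's dilemma strategies via coalitional better
    responses. Provides exact-edge-count Erdos-Renyi and Watts-Strogatz
    graph generators, exhaustive enumeration and uniform sampling of
    connected (or clique) coalitions, the coalitional update rule with its
    tie-breaking semantics, and experiment drivers for collaboration /
    edge-density parameter sweeps, long-run time series, per-node
    cooperation maps and collaboration on/off schedules, with fully
    seeded, manifest-backed CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
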