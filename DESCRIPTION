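Package: embednet
Title: Structural Embeddedness and Stimulus-Evoked Responses in Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the structural embeddedness of neurons -- their
    out-degree, k-shell-out index and betweenness centrality -- determines the
    impact of their activity on a recurrent spiking network. Provides a
    multifractal (generating-measure) network generator spanning a wide range of
    topologies, Erdos-Renyi controls, a modular-hub fixture and a 14-node toy
    network; per-node embeddedness metrics and the small-world index; a fast
    leaky integrate-and-fire network simulator with Poisson background and timed
    stimulus injection; a deterministic threshold-cascade model contrasting
    regular and bursting activation spread; and an experiment/analysis layer
    that stimulates embeddedness-stratified subpopulations, quantifies the
    evoked population response (PSTH peak, total spike count) and correlates it
    with embeddedness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
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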