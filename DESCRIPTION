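Package: plastinet
Title: Calcium-Based Synaptic Plasticity Simulation and Network-Structure
    Analysis of Plastic Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulation and analysis of long-term plasticity in
    cortical excitatory networks. Implements a calcium-based bistable
    synaptic efficacy model with per-synapse depression and potentiation
    thresholds derived from single-spike calcium transients, driven by a
    reduced kernel model of local dendritic voltage; pair-based STDP and
    high-dimensional random-walk control models; detection of functional
    cell assemblies from spike trains (shuffle-based significance, Ward
    clustering, Davies-Bouldin model selection); directed-simplex counts
    and k-edge indegree edge centrality; dendritic synapse-cluster
    statistics with an exponential inter-synapse-distance null and
    Michelson-contrast change likelihoods; spike-time reliability and
    input-output distance correlations (exact earth mover's distance);
    plus seeded generators for all synthetic inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    clue,
    vegan,
    withr,
    rhdf5,
    knitr
Config/testthat/edition: 3
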