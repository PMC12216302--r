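Package: thalamap
Title: Connectional Domain Detection and Dendritic Morphometry for the
    Anterior Thalamic Nuclei
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for grid-based analysis of axonal tracer labeling and for
    quantitative dendritic morphology of thalamic projection neurons.
    Builds injection-by-grid connectivity matrices from segmented tracer
    label, detects connectional domains by Louvain modularity maximization
    on the weighted bipartite injection/grid graph, normalizes whole-brain
    projection profiles (connectivity fraction and density) and clusters
    them hierarchically, parses and resamples SWC neuron reconstructions,
    computes per-neuron morphometric features (total length, branch count,
    height, maximum path distance, average branch order, partition
    asymmetry, Sholl profiles) and center-tropism statistics (average
    angular deviation from a nucleus center, proportion of wiring closer to
    the center than the soma, edge versus non-edge classification), and
    provides seeded synthetic generators for neurons, cohorts, feature
    mixtures, grid matrices, and projection count tables so the whole
    pipeline is testable without imaging data.
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
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
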