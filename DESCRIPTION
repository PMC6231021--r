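Package: nri
Title: Neural Reconstruction Integrity Scoring for Connectome Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Scores how well a reconstructed neural connectivity graph
    preserves the intracellular synapse-to-synapse paths of a ground-truth
    graph. Implements the Neural Reconstruction Integrity (NRI) metric as an
    f-score over matched synaptic-terminal path pairs, together with a
    terminal-based adapted Rand index and a normalized variation of
    information for comparison. Synapses are reconciled between the two
    graphs by minimum-distance bipartite assignment of their centroids with
    an unassignment distance cap. Also provides a synthetic cortical-network
    generator (neurons grown as trees of cylindrical process segments with
    distance-dependent synapse placement) and four reconstruction-error
    perturbation models (synapse deletion and insertion, neuron split and
    merge) for evaluating reconstruction metrics under controlled error
    regimes.
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
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
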