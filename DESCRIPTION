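Package: hexpin
Title: Column and Layer Coordinate Frames for Optic-Lobe Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to turn synapse-level connectome exports (neuron, synapse
    and connection tables) into a cell-type inventory anchored to a
    retinotopic coordinate system. Builds hexagonal column coordinates from
    synapse point clouds, fits curved column centre lines ("pins") and
    depth-based layer schemes, clusters neurons into types by connectivity
    and morphology features, assigns neurons to anchor columns by maximum
    weight bipartite matching, computes spatial coverage and tiling metrics
    with knee-point trimming of per-column synapse counts, aggregates
    per-synapse neurotransmitter probabilities into per-cell and per-type
    calls, and summarises weighted region-to-region connectivity. A
    synthetic optic-lobe generator with planted ground truth supports
    end-to-end testing without access to the full dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
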