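Package: pathlink
Title: Path-Based Similarity Indices for Link Prediction in Complex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts missing links in simple undirected networks (protein
    interaction, neural, metabolic, social) with degree-aware similarity
    indices. Implements eight local indices (common neighbours, resource
    allocation, Adamic-Adar, Sorensen, Salton, Leicht-Holme-Newman, hub
    promoted, hub depressed) together with their global (infinite damped
    walk-series, evaluated through matrix resolvents) and quasi-local
    (walk-series truncated at length three) extensions, plus the Katz and
    local-path baselines. Includes edge-list I/O for KONECT/SNAP style
    files, topology statistics, train/probe AUC and precision evaluation
    with repeated-run experiment harnesses, seeded synthetic-graph
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
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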