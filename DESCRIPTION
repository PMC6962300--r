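Package: connectoflux
Title: Information Transfer and Energy Analysis of Brain Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates one-step ternary signal propagation on thresholded
    weighted brain connectivity matrices and quantifies the resulting network
    states: plug-in mutual information between random stimuli and responses,
    wiring cost, bias-free Hopfield energy and activity cost with their
    normalized ratios, Hamming-style activation-pattern overlap, largest
    connected component and transitivity, and an upper-truncated power-law
    fit to node-strength distributions selected by Kolmogorov-Smirnov
    distance. Includes threshold/probability sweep orchestration across
    subject collections, cross-quantity correlation summaries, and synthetic
    generators (uniform-weight null matrices, hub/community factor-model
    correlation matrices, direct strength-distribution samples) so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
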