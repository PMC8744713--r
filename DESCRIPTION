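Package: espsim
Title: Ecological Security Patterns and Constrained Urban Growth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ecological security patterns from categorical land-use
    rasters and simulates future urban expansion under unconstrained and
    pattern-constrained scenarios. Implements morphological spatial pattern
    analysis (MSPA) of habitat masks, the probability-of-connectivity index
    (PC/dPC) for ecological-source selection, least-cost ecological corridors
    on a land-use and relief resistance surface with gravity-model ranking,
    Markov-chain land demand projection, a neural-network cellular-automata
    allocator with neighborhood effects, adaptive inertia, conversion
    constraints and roulette competition, and urban-expansion analytics
    (annual increase index, annual growth rate, quadrant and ring zonings,
    kappa validation). Includes a seeded synthetic-landscape generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    nnet,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
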