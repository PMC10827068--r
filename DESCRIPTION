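Package: ldenet
Title: Logic-Based Differential Equation Modeling of Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct, simulate and perturb logic-based differential
    equation (LDE) models of signaling and gene-regulatory networks.
    Models are defined as species (genes, proteins or processes carrying a
    continuous normalized activity) connected by activating or inhibiting
    reactions; each reaction contributes a normalized Hill flux and fluxes
    converging on a species are merged with a continuous fuzzy OR. The
    package parses the two-sheet spreadsheet model format, runs staged
    simulation protocols that mirror an interactive change-and-simulate
    workflow, performs systematic in-silico knockout screens, and exports
    networks as Cytoscape SIF edge tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    deSolve,
    readxl,
    zip,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
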