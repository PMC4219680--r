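Package: stochslice
Title: Slicing, Stochastic Simulation and Debugging of SBML Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostic toolkit for stochastic simulation of SBML-encoded
    reaction networks. Builds a cofactor-aware directed reaction dependency
    graph, extracts model slices (the sub-model relevant to a sink species,
    optionally constrained to a source species), simulates models with the
    Gillespie direct-method stochastic simulation algorithm, and layers
    software-debugger primitives over the simulation: breakpoints,
    conditional breakpoints, watch snapshots, runtime edits, instruction
    skipping and deadlock diagnosis. Also computes forward-algorithm-style
    predictive reaction weights for reactions whose reactants are not yet
    available, and stabilization/behavior-difference metrics for comparing
    reduced models against their originals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
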