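Package: yeastpop
Title: Coarse-Grained Multiscale Simulation of Budding Yeast Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-module coarse-grained model of growing budding yeast
    populations. A proteome-allocation solver maximizes the balanced
    exponential growth rate for a given carbon source and fermentative
    ratio, and exports the per-ribosome synthesis rate and RNA/protein
    ratio to a single-cell growth and cell-cycle simulator. An
    agent-based engine grows pedigree-structured populations to
    flow-cytometry scale (~50,000 cells), injects division noise, and
    exposes protein-content distributions, temporal parameters,
    one-at-a-time sensitivity scans, the population-kinetics calculator
    for asymmetrically dividing cells, and a 1024-channel histogram
    aligner for comparison with experimental flow-cytometry protein
    distributions. Includes a molecular Whi5/SBF G1/S controller that
    can replace the coarse G1 trigger, plus canned mutant and
    nutrient-series scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
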