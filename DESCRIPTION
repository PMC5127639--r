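Package: ftkd
Title: Epidermal Tight-Junction Turnover on a Flattened-Tetrakaidecahedron Lattice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation and morphometry of tight-junction (TJ)
    turnover in the stratum granulosum of the epidermis. Cells are modelled as
    flattened Kelvin tetrakaidecahedra (f-TKD) stacked in an interdigitated
    space-filling lattice; a discrete-time stochastic engine implements the
    local differentiation rules that drive SG2-to-SG1 turnover with dynamic
    TJ replacement. The package extracts the en face TJ honeycomb from
    simulation snapshots, classifies bicellular and tricellular junctions and
    single-, exterior- and interior-class polygons, audits barrier continuity,
    and reproduces the morphometric statistics (double-edged polygon fraction,
    polygon areas and relative Z positions, residence times) used to
    characterise TJ barrier homeostasis. A synthetic-microscopy generator
    produces noisy honeycomb meshes with planted ground truth for validating
    every measurement procedure without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    mgcv,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
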