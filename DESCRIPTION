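Package: vsmcabm
Title: Agent-Based Simulation of Vascular Smooth Muscle Cell Growth Under
    Cyclic Strain and Structural Cues
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A 2D lattice-free agent-based simulator of vascular smooth
    muscle cell populations responding jointly to cyclic substrate strain
    (strain avoidance) and collagen-fiber structural cues. Decomposes an
    applied cyclic strain into principal amplitude and direction via Mohr's
    circle, synthesises smooth continuous fiber-orientation fields from von
    Mises draws interpolated over a Delaunay triangulation, updates cell
    orientations with a blended mechanical/structural rate law, and couples
    per-cell effective strain to stochastic apoptosis and age-gated
    proliferation with collision-checked daughter placement. Includes the
    grid-search calibration workflows (baseline apoptosis sweep, strain
    response grid, rotation-constant sweeps) against packaged experimental
    reference tables, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
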