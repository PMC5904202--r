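Package: tcrflex
Title: Rigidity, Elastic Network Modes, and Geometric Simulation of TCR
    CDR Loop Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the intrinsic flexibility of unbound T cell
    receptor (TCR) complementarity determining region (CDR) loops from crystal
    structures. Provides PDB input/output with unit-cell metadata, Kabsch
    superposition and per-residue displacement profiles across multi-crystal
    ensembles, crystal lattice contact detection from space-group symmetry,
    an all-atom constraint network with geometry-scored hydrogen bonds and
    hydrophobic tethers, body-bar pebble-game rigidity analysis, Calpha
    elastic-network normal modes, template-based geometric simulation of
    mode-biased flexible motion to its jamming limit, and per-loop apex
    amplitude reporting over the generated conformer ensembles. Includes
    seed-deterministic synthetic structure generators so every stage can be
    exercised without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
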