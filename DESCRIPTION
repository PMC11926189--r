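Package: PolysomeTracer
Title: Polysome Tracing and Ribosome Heterogeneity Analysis from
    Subtomogram Particle Poses
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Traces polysomes in cellular cryo-electron tomograms from
    refined subtomogram particle poses. Maps user-defined mRNA entry and
    exit markers from the subtomogram-average frame into tomogram
    coordinates, builds directed exit-to-entry nearest-neighbour link
    graphs, resolves shared neighbours and cycles, and assembles polysome
    chains. Summarises ribosome compositional heterogeneity (per-polysome
    class fractions, per-cell occupancies, exit-to-entry distance
    distributions with cell-to-cell confidence bands and two-sample
    tests). Includes a synthetic particle-scene generator with planted
    ground truth, and a structural-interface module (Kabsch superposition
    RMSD, Shrake-Rupley solvent accessibility, buried interface areas and
    contact residues) for quantifying dual protein binding sites in
    atomic models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
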