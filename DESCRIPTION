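Package: enmaflex
Title: Elastic-Network Normal-Mode Flexibility Analysis with
    Rotation-Translation Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds single-parameter (Tirion) elastic networks from protein
    structures, solves their normal modes directly or through the
    rotation-translation-block (RTB) projection, and turns the slow modes
    into per-residue flexibility profiles: mean-square fluctuations,
    relative RMSF, and computed B-factors rescaled against crystallographic
    data. Includes crystallographic symmetry expansion for head-to-tail
    oligomer construction, region and radial-layer flexibility reports, a
    coarse bilayer-slab surrogate for membrane-embedded analysis,
    mode-trajectory export as multi-model PDB, and synthetic structure
    generators with analytically known spectra for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    Matrix,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
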