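Package: vesselmech
Title: Strain Decomposition, Image Quantification and Actomyosin Cortex
    Simulation for Endothelial Vessel Constriction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for studying how endothelial cells drive
    blood vessel constriction. Decomposes vessel remodelling between two
    timepoints into cell-deformation and cell-number (rearrangement) strains
    along the radial and axial axes; measures vessel diameter from wall-peak
    intensity profiles, junction-to-cortex intensity ratios, and post-ablation
    recoil velocities from kymographs; classifies cortical actin textures as
    circumferential, mesh or longitudinal with a structure-tensor heuristic;
    and simulates a two-dimensional coarse-grained actomyosin cortex
    (filaments, motors, crosslinkers, deformable membranes) with virial-stress
    and circumferential-alignment readouts. Seeded synthetic-data generators
    emulate every input, so the full pipeline runs without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    pracma,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
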