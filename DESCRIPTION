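Package: punctaflow
Title: Puncta Segmentation, Object-Based Colocalization, Mobility and
    Calcium-Puff Analysis for TIRF Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing punctate fluorescence microscopy data of the
    kind used to study tethered receptor clusters and local calcium signals:
    seeded radial-growth spot segmentation with sub-pixel centroids,
    object-based colocalization by nearest-neighbour centre-to-centre
    distances with object-randomization null models, mask-based Manders
    split coefficients, single-particle linking with anomalous-diffusion
    (MSD exponent) mobility classification, FRAP mobile-fraction estimation,
    calcium-puff detection and site mapping on dF/F0 movies, and
    fluorescence-to-calcium calibration. Includes a synthetic-data generator
    producing TIRF-like image stacks with known ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    EBImage,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization
RoxygenNote: 7.3.3
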