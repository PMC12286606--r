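Package: ribbonmotion
Title: Trajectory and Image Analysis of Presynaptic Ribbon Transport in Hair Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the intracellular transport of presynaptic ribbon
    precursors and microtubule plus-end (EB3) comets in developing sensory
    hair cells from 4D fluorescence microscopy. Provides motion-predictive
    track linking with gap closing, time-averaged mean-squared-displacement
    analysis with power-law exponent (alpha) classification of confined,
    Brownian and directed motion, displacement-based track classification,
    track-angle polarity analysis relative to the apical-basal cell axis,
    automated scoring of puncta fusion events, 3D puncta segmentation and
    apical/basal counting, 2D area quantification, and kinocilium-height
    developmental staging. A synthetic-data module generates labeled
    trajectories, comet fields, fusion scenarios and rendered image stacks
    so that every analysis stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
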