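Package: astroage
Title: Astrocyte Ageing Morphometry, Calcium Events and Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies age-related structural and functional remodelling of
    hippocampal astrocytes from two-photon image stacks, time-lapse calcium
    movies and patch-clamp / field-potential recordings. Implements photon-count
    calibration of PMT images, coherence-enhancing diffusion and hysteresis
    binarization, automated 3D skeletonization with Sholl analysis and domain
    area, volume-fraction estimation of optically unresolved perisynaptic
    processes, spatiotemporal (x-y-t) calcium event segmentation, input
    resistance and K+/glutamate-transporter current decomposition, and LTP
    quantification. Every stage is paired with a seeded synthetic-data
    generator that emits machine-readable ground truth, so each estimator is
    verifiable by parameter recovery on planted values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    tiff,
    EBImage,
    minpack.lm,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
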