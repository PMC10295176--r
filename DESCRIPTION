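Package: smss
Title: Spatial Statistics for Object-Based Colocalization with Moving Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Object-based colocalization of nanoparticles with moving
    vesicles in two-channel fluorescence microscopy. Implements bivariate
    spatial summary functions (nearest-neighbour function G12, Ripley's
    K12 with translation edge correction, pair-correlation function g12)
    on polygonal regions of interest with holes, together with Monte-Carlo
    reference envelopes for complete spatial randomness and for transport
    with lognormal jump distances. Supporting tools cover a-trous wavelet
    spot detection with watershed splitting, single-particle tracking by
    linear assignment with gap closing, trajectory feature extraction and
    motion classification via t-SNE and DBSCAN, ensemble mean-squared
    displacement analysis with power-law fits, and seed-deterministic
    synthetic data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    EBImage,
    tiff,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
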