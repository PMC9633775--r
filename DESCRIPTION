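Package: gradflow
Title: Structural and Neuromodulatory Shaping of Dynamic Functional
    Connectivity Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how structural connectivity and
    neuromodulatory gene-expression similarity shape static and
    arousal-dependent dynamic functional-connectivity gradients.
    Implements diffusion-map embedding of thresholded normalized-angle
    affinity matrices, Procrustes alignment and fingerprinting of
    gradient sets, pupil- and template-based arousal indices, dynamic
    conditional correlation (GARCH/DCC) connectivity, general-linear-model
    variance partitioning with shuffle-based reduced models, and
    variogram-matching spatial-autocorrelation surrogate maps. Ships a
    synthetic-cohort generator with planted gradients, arousal dynamics
    and receptor loadings so the full pipeline can be exercised and
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
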