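Package: rhythmevo
Title: Evolutionary Analysis of Collective and Individual Activity Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying ultradian rest/activity rhythms of social
    insect colonies and isolated individuals, and for comparing how the
    resulting rhythm traits evolve across species on a time-calibrated
    phylogeny. Activity is extracted from image sequences by adaptive-threshold
    frame differencing, dense optical flow, or centroid tracking; each series
    is summarized by its dominant oscillation period and a wavelet-based
    rhythmicity (coherence factor) computed from a continuous wavelet
    periodogram. Species tip values are estimated with mixed models, and
    evolutionary inference covers Brownian-motion rate estimation with
    bootstrap rate comparison, phylogenetic generalized least squares (with an
    intraspecific-variation sensitivity analysis), and multivariate phenotypic
    disparity. A synthetic-data module (noise-driven FitzHugh-Nagumo
    oscillators, blob image stacks, open-field tracks, Brownian trait
    simulation on pure-birth trees) provides study-shaped datasets with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nlme,
    phytools,
    deSolve,
    withr,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
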