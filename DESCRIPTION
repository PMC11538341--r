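Package: lociloc3d
Title: Astigmatism-Based 3D Localization and Tracking of Chromosomal Loci in Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for super-resolved 3D localization and
    tracking of fluorescently labelled chromosomal loci in rod-shaped
    bacteria imaged with an astigmatic point spread function (PSF). The
    package calibrates a piecewise cubic-spline model of the PSF from bead
    z-stacks and computes Cramer-Rao lower bounds on localization
    precision; models heterogeneous in-cell fluorescence background as
    boundary-distance-conditioned gamma distributions; calibrates a
    per-pixel sCMOS camera noise model; simulates ground-truth-labelled
    training frames; trains a convolutional localizer with a
    count/cross-entropy/localization/PSF compound loss; decodes network
    outputs into localization tables; maps localizations into internal
    cell coordinates (long axis, signed short axis, radius, angle) via
    backbone fits and tilt-plane correction; and analyses locus motion
    with mean-squared-displacement power-law fits, confinement plateaus
    and sister-locus angle correlations. Seeded synthetic generators
    (astigmatic bead stacks, spherocylinder cell masks, fractional
    Brownian motion, Ornstein-Uhlenbeck trajectories) provide drop-in
    replacements for every experimental input.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    tiff,
    EBImage,
    fitdistrplus,
    minpack.lm,
    MASS,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
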