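Package: gwnr
Title: Geographically Weighted Nonparametric Regression with a Mixed
    Truncated-Spline and Fourier Basis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the global mixed nonparametric regression (MNR) model and
    its geographically weighted extension (GWNR), in which every regression
    coefficient of a shared truncated-power-spline plus Fourier-series basis
    is re-estimated at each spatial location by kernel-weighted least
    squares.  Provides the goodness-of-fit F test that decides whether the
    location-varying coefficients fit significantly better than the global
    model, using Satterthwaite scaled chi-square approximations to the error
    sums of squares with hat-matrix-trace degrees of freedom.  Includes
    spatial kernels with fixed or adaptive bandwidth, leave-one-out
    cross-validation bandwidth selection, a seeded synthetic-data generator,
    and a Monte-Carlo harness for size and power studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    geosphere,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
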