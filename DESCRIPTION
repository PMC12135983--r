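Package: cvsansGP
Title: Gaussian Process Estimation of Partial Scattering Functions from
    Contrast-Variation SANS Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes contrast-variation small-angle neutron scattering
    (CV-SANS) intensity curves into partial scattering functions S_ij(Q)
    using Gaussian process regression with a smoothness prior along the Q
    axis. Provides the exact linear-Gaussian posterior (means, error bars and
    full covariance) under Gaussian and Matern (3/2, 5/2) kernels with an
    additive white kernel, kernel-parameter selection by log marginal
    likelihood or MAP estimation under a hyper-prior, the per-Q weighted
    least-squares baseline with propagated errors, a core-shell sphere
    simulator for validation studies, and delimited-text readers and writers
    for reduced SANS data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
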