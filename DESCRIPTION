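Package: saxsim
Title: Simulation of Small-Angle Scattering from Geometric Bead Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds multi-contrast particle models from geometric subunits as
    uniform-density Monte-Carlo point clouds, computes contrast-weighted pair
    distance distributions and small-angle scattering intensities via the
    binned Debye transform, and adds polydispersity, hard-sphere or fractal
    structure factors with the decoupling approximation, interface roughness
    and realistic synchrotron-like noise to produce simulated SAXS data.
    Includes closed-form sphere, cylinder and core-shell cylinder form
    factors and a chi-square fitting harness for validating bead models
    against analytical scattering models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    pracma,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    bio3d,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
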