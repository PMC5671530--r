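Package: npwtox
Title: Multiscale Simulation of Negative Pressure Wound Therapy and Tissue Oxygenation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulation of negative pressure wound therapy
    (NPWT) applied to a trans-femoral residual limb, coupled to a
    capillary-scale model of tissue oxygenation. Provides a parametric
    axisymmetric limb/wound/foam geometry generator, a nonlinear
    hyperelastic finite-element solver (Mooney-Rivlin muscle, Ogden-type
    hyperfoam filler) with follower pressure loads, principal-stress
    summaries over regions of interest, a Krogh-cylinder capillary model
    (plane-strain structural solve plus oxygen diffusion extended with a
    pressure-stress drift term), and a pipeline that maps suction-induced
    tissue stresses to changes of oxygenated tissue area around the wound
    bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    Matrix,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
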