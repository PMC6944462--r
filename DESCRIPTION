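Package: tctrecon
Title: Limited-Angle Translational CT Simulation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and reconstruction toolkit for translational computed
    tomography (TCT), a low-cost scanning geometry in which the X-ray source
    and a flat-panel detector translate linearly in opposite directions and
    are manually rotated between 30-degree segments. Provides the scanning
    geometry builder, a matrix-free Siddon ray-driven projector with exact
    adjoint, SART (simultaneous algebraic reconstruction technique) and
    filtered back projection reconstruction, synthetic phantom and sinogram
    simulation with Gaussian projection noise, a U-net convolutional network
    (with momentum-SGD training) for suppressing limited-angle artifacts in
    SART reconstructions, and PSNR/SSIM image quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
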