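Package: bctsim
Type: Package
Title: Energy Optimization for Monochromatic Parallel-Beam Breast CT
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for finding the X-ray energy that maximizes the
    contrast-to-noise ratio (CNR) at fixed mean glandular dose in
    monochromatic parallel-beam breast computed tomography. Provides
    tissue and air attenuation data with mixture rules, a Monte-Carlo
    estimator of the normalized glandular dose coefficient for a
    cylindrical breast, a closed-form CNR model for filtered
    back-projection built on the noise power spectrum of CT images, a
    Poisson-noise sinogram simulator for an ideal photon-counting
    detector, FBP/SART/SIRT reconstruction with photon-starvation
    correction, and ROI-based CNR measurement on reconstructed slices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
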