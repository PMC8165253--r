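Package: PAmeso
Title: Simulation, Reconstruction and Analysis for Planar-Scan Photoacoustic Mesoscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for planar raster-scan photoacoustic mesoscopy with a
    wide-band Fabry-Perot ultrasound sensor. Provides forward simulation of
    photoacoustic N-wave signals from sphere-based absorber phantoms (wire
    targets and branching artery/vein trees), sensor-bench computations
    (frequency response, -3 dB bandwidth, angular directivity, noise-equivalent
    pressure), 3D universal back-projection reconstruction with single or dual
    speed-of-sound analytic time of flight, Hilbert-transform envelope
    detection, Gaussian line-spread-function resolution analysis, depth-coded
    maximum intensity projections, hysteresis vessel segmentation,
    diffusion-approximation fluence compensation and dual-wavelength
    artery/vein difference imaging. All physical quantities are in SI units.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    Rcpp,
    minpack.lm,
    RNifti,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
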