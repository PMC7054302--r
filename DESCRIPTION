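Package: hyseclass
Title: Online Color Classification for Line-Scanning Hyperspectral Endoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pixel-wise color classification of line-scanning
    hyperspectral endoscopy (HySE) data. Provides ENVI-format input/output
    for hypercubes and label rasters, white/dark reflectance calibration,
    median denoising, spectral binning and patch wrapping, a pixel-wise
    convolutional neural network classifier trained by momentum stochastic
    gradient descent (plus a slice-wise variant), conventional spectral
    baselines (Pearson correlation matching, supervised and unsupervised
    spectral unmixing, one-vs-one support vector machines), the average
    classification accuracy metric with per-slice timing, and a synthetic
    Macbeth-chart hypercube simulator with planar and tube (lumen)
    geometries so the whole pipeline can be exercised without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    e1071,
    jsonlite,
    pracma,
    png,
    stats
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
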