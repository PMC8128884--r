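Package: cellmotion
Title: Non-Invasive Quantification of Cell and Colony Motion in
    Time-Lapse Phase-Contrast Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the collective motion of cultured keratinocyte
    cells and colonies from time-lapse phase-contrast image sequences
    without labels or fixation.  Each frame is segmented into cell and
    background area by Gaussian smoothing, Sobel edge magnitude and
    Chan-Vese active-contour binarisation; dense optical flow between
    consecutive frames yields a per-pair motion speed (MS) over the
    segmented cell area, averaged into a mean motion speed (MMS) in
    micrometres per hour.  Also provides confluency (growth-fraction)
    series, population-doubling metrics (PD, PDT), threshold-based
    quality screening of cultures, Spearman correlation statistics,
    and a synthetic time-lapse generator with exact ground-truth masks
    and displacement fields for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
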