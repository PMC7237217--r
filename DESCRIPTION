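Package: centrofind
Title: Cell-Centre Detection in 3D Microscopy Volumes by Proximity-Map
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects cell centres in 3D and 3D+time fluorescence microscopy
    volumes from sparse 2D point-and-click annotations.  A random-forest
    pixel regressor is trained to predict a proximity map (nearness to a
    cell centre, built as the maximum of Gaussian kernels placed on
    annotated centres) from a multiscale 2D filter bank; per-plane
    predictions are stacked into a 3D volume, enhanced with a
    determinant-of-Hessian blob filter tuned to the expected object size,
    and discrete centres are extracted by thresholded 3D maxima finding.
    Includes keyframed polygon ROIs with interpolation across planes and
    timepoints, precision/recall/F1 scoring of detections against ground
    truth, a synthetic phantom generator with controlled clustering and
    signal-to-noise ratio, cell tracking with division-rate and
    cell-cycle-length estimation, and refinement of detections into
    instance segmentations via active contours and marker-based watershed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
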