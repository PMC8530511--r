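Package: rpemorph
Title: 3D Morphometry of Epithelial Flattening in the Developing Eye
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Morphometric analysis of fluorescence time-lapse stacks of the
    folding optic vesicle, centred on quantifying flattening of the retinal
    pigment epithelium (RPE). Provides segmentation of tissue signal (median
    filtering, top-hat background neutralization, median-intensity
    thresholding), tissue volume, fitted-surface area and volume/surface
    thickness, block-wise discretization with ciliary-marginal-zone
    exclusion, whole-eye convex-hull volume, growth-slope kinetics,
    cell-shape and invagination-angle measurements, and proliferation-index
    scoring. A synthetic voxel-phantom generator with exact analytic ground
    truth drives validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
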