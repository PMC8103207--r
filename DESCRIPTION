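Package: paretodose
Title: Priority-Conditioned Dose Prediction and Pareto-Surface Evaluation
    for Prostate VMAT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise dose prediction for prostate volumetric modulated
    arc therapy (VMAT) conditioned on optimization priorities. Builds an
    analytic dose initialization from planning-target-volume distance maps,
    refines it with a six-block voxel-wise residual network over contiguous
    and atrous (dilated) patch features, and evaluates predicted
    multi-criteria trade-off (Pareto) surfaces with matched root-mean-square
    error, Hausdorff distance, average projected distance and average
    nearest-point distance. Includes a synthetic pelvic-phantom cohort
    generator with surrogate treatment-planning-system doses, masked-RMSE
    training with diagonal slice batching and Adam, and repeated k-fold and
    rotating-subset cross-validation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
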