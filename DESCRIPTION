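Package: canopyield
Title: Field-Scale Corn Yield Prediction from Multispectral Imagery, Soil and Terrain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An analysis pipeline for predicting corn grain yield at
    production-field scale from co-registered multispectral reflectance
    rasters, gridded soil properties, and terrain. Implements bare-ground
    masking by red-edge NDVI thresholding, Thiessen-polygon zonal feature
    extraction around harvester yield points, a registry of 35 vegetation,
    color-space and red-edge wavelength indices, and a comparison of
    multiple linear regression, random forest, and gradient-boosted
    ensembles across crop growth stages, including iterative feature
    selection and the statistics used to compare methods. A seed-driven
    synthetic-field generator provides spatially structured soil, terrain,
    canopy reflectance and harvester yield data with known ground truth
    for validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
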