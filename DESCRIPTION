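Package: loggrid
Title: Grid-Cell Monitoring of Selective Logging and Deforestation from
    Medium-Resolution Reflectance Imagery
Version: 0.1.0
Authors@R: person("loggrid", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An integrated workflow for annual monitoring of deforestation
    and selective-logging disturbance in tropical forests from co-registered
    multi-band reflectance imagery (Landsat-class, 30 m). Provides
    object-based forest/non-forest masking by multiresolution region
    merging, relative radiometric normalization over pseudo-invariant
    features, fully constrained linear spectral mixture analysis producing
    soil/vegetation/shade fraction images, soil-fraction thresholding of
    logging evidence inside the forest mask, fixed 300 m grid-cell
    disturbance-intensity accounting with annual rates, land-cover change
    matrices and disturbance recurrence, stratified-sampling accuracy
    assessment with error matrices, and a synthetic-landscape simulator
    with per-pixel truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
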