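Package: prfident
Title: Image Identification from Visual-Cortex fMRI with Population Receptive Field Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates circular-Gaussian population receptive fields (pRFs) from
    bar-aperture retinotopic mapping fMRI time series, predicts voxel response
    profiles to arbitrary candidate images from pRF-weighted stimulus overlap or
    pRF-weighted contrast energy, and identifies which image was presented by
    correlating measured GLM response profiles against the model predictions.
    Includes block-design GLM estimation, voxel-selection filters, bootstrap
    accuracy curves over candidate-set size, per-image identification
    confidence scores, and a forward simulator of retinotopically organized
    voxel populations for validation without scanner data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse, RNifti, png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
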