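Package: spinesanity
Title: Vertebra Detection and Identification in CT with a Domain Sanity Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage localization and identification of vertebra centroids in
    3D computed-tomography volumes, with unsupervised domain adaptation driven
    by a four-term anatomical "domain sanity" loss: ascending vertebra order
    along the spine, column-wise label consistency in the sagittal plane,
    inter-centroid distances checked against literature reference values, and
    label consistency over an unsupervised weak vertebra segmentation built
    with graph-based (Felzenszwalb-Huttenlocher) image segmentation. Includes
    connected-component post-processing of the spine detection stage, sparse
    (centroid) to dense (per-voxel) label conversion and median-based recovery,
    evaluation metrics (per-pixel classification rate, 20 mm identification
    rate, distance statistics, overlap scores), and a synthetic spine-phantom
    generator with a shifted target-domain variant so the whole pipeline can be
    exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
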