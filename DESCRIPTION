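Package: dabquant
Title: Unsupervised Quantification of DAB Immunostaining in H-DAB Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies DAB (3,3'-diaminobenzidine) staining on
    brightfield photomicrographs of hematoxylin-DAB stained tissue sections,
    with defaults tuned for the thin elongated strips formed by reconstructed
    human epidermis. The pipeline performs Reinhard color normalization in the
    l-alpha-beta opponent space, Ruifrok-Johnston color deconvolution with
    H-DAB stain vectors, Otsu plus morphological tissue masking, automatic
    rotation of the tissue strip to horizontal by maximizing the peak of the
    row-sum boundary profile, rejection of unstained samples via the average
    proportion (AP) statistic with ROC/Youden calibration, and k-means
    segmentation of DAB-positive regions with Davies-Bouldin model selection.
    Results are reported as percent DAB occupancy of the tissue area, with
    contour overlays and batch CSV reports. A seeded Beer-Lambert synthetic
    image generator provides ground-truth fixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
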