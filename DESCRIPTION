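Package: lamcyst
Title: Automated Segmentation of Pulmonary Cysts in Lymphangioleiomyomatosis
    Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated quantification of pulmonary cyst burden in chest
    CT of lymphangioleiomyomatosis (LAM) patients.  Cysts are identified by a
    locally adaptive radiodensity threshold set midway between the local
    non-cystic parenchyma density, estimated with a Gaussian-weighted local
    smoothed-histogram mode filter, and a per-slice intra-lung air reference
    derived from the segmented large airways and the external air background.
    Includes automated lung, trachea and large-airway segmentation, kernel-
    conditional resolution harmonization, a synthetic chest-phantom generator
    with ground-truth masks for validation, and longitudinal-consistency and
    pulmonary-function correlation metrics for cyst-score time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
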