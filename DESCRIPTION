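Package: gaitscreen
Title: Video-Based Gait Screening for Adult Spinal Deformity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-stage video pipeline for classifying walking patients as
    adult spinal deformity (ASD) versus other spinal disorders. A detection
    stage locates the patient in each frame, distinguishes them from a
    later-entering second person by nearest-center tracking, and emits
    square patient-centered crops. A classification stage scores 1-second,
    8-frame clips with a bottleneck-block 3D residual convolutional network,
    trained with Adam, early stopping and learning-rate halving, and
    evaluated under patient-level stratified group cross-validation with
    accuracy, F1 and AUROC. Includes a deterministic synthetic walking-scene
    generator for end-to-end testing without clinical data, and Grad-CAM++
    attention maps fused across frames for model inspection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
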