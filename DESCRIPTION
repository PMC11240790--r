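Package: pdacascade
Title: Multi-Stage Coarse-to-Fine Detection of Pancreatic Head Tumors on CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A segmentation-for-detection cascade for pancreatic head tumors
    on abdominal CT. The pipeline localizes the pancreas on a low-resolution
    volume, segments it precisely on a high-resolution crop, segments the
    pancreatic duct and common bile duct with an anatomical plausibility
    filter, and feeds the CT crop together with these secondary-feature
    channels into a residual 3D U-Net tumor detector; fold ensembles yield a
    case-level cancer score. Includes a synthetic abdominal CT phantom
    generator (pancreas, ducts, duct dilation upstream of a planted head
    tumor, hypo/iso/hyper attenuation classes), a full training stack
    (patient-level splits, augmentation, soft-Dice + cross-entropy), and the
    evaluation suite (DSC, ROC/AUC, localization overlap, subgroup reports).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tibble,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
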