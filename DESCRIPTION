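Package: lungseg
Title: Weakly Supervised Lung Parenchyma Segmentation for Thoracic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments lung parenchyma in thoracic CT volumes without manual
    annotation. Training labels are generated by clustering image-patch
    intensity statistics (two-class k-means on patch mean and minimum
    intensity, cross-shaped verification, volume intersection, and connected
    component analysis), a compact single-convolution-layer neural network is
    fitted to the resulting balanced 32x32 patch dataset, and whole volumes
    are segmented voxel-wise or patch-wise with maximum-connected-component
    and hole-filling post-processing. Includes a synthetic thoracic phantom
    generator with analytic ground truth, segmentation quality metrics (Dice
    coefficient, Hausdorff distance, sensitivity/specificity, ROC/AUC,
    macro-averaged F-score), stratified cross-validation, and hyper-parameter
    sweep harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    pROC
Config/testthat/edition: 3
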