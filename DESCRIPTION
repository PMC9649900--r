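Package: scintiseg
Title: Semi-Supervised Segmentation of Bone-Metastasis Lesions in Bone Scan Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and delineates bone-metastasis lesions in low-resolution
    planar bone-scan (skeletal scintigraphy) images. Implements a recurrent
    feature-extraction network built from dilated residual convolution blocks
    and an inception block, trained with a semi-supervised loss that combines
    a Chan-Vese-style unsupervised region energy with a label-guided region
    plus total-variation smoothness term. Includes count-matrix and LabelMe
    polygon I/O, thorax cropping and dual-view (anterior/posterior)
    aggregation, inter-annotator agreement gating and consensus ground-truth
    selection, geometric and DCGAN-based data augmentation, patient-grouped
    dataset splitting, repeated evaluation with Dice, class pixel accuracy and
    recall, lesion boundary extraction, and a synthetic dual-view phantom
    generator so the full pipeline is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
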