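Package: cnnres
Title: Residual Encoder-Decoder Networks for Ischemic Stroke Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds, trains and evaluates CNN-Res, a U-shaped convolutional
    network with pre-activation residual blocks and a bottleneck compression
    layer, for binary segmentation of ischemic stroke lesions on 2-D MRI
    slices. Includes a synthetic MRI phantom generator with co-registered
    DWI/FLAIR-like modalities and lesion masks, NIfTI volume input/output,
    brain-centering and lesion-slice preprocessing, the dihedral
    rotation/flip augmentation scheme, a soft-Dice training objective with
    Adam optimisation, exact layer-by-layer parameter accounting with a
    block-convention reconciliation report, a pinned reference U-Net
    baseline, and Dice-coefficient evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    generics,
    tibble,
    ggplot2,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
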