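Package: fedsegsim
Title: Desk-Scale Federated Learning Simulation for Multi-Site Brain
    Tumor Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the complete federated-learning workflow used to
    train glioblastoma sub-compartment segmentation models across many
    imaging sites: BraTS-convention label algebra for the nested
    enhancing-tumor / tumor-core / whole-tumor regions, a configurable 3D
    residual U-Net trained with the mirrored generalized Dice loss,
    data-size-weighted federated averaging (FedAvg) rounds, singlet and
    triplet consensus-model selection, and per-site validation monitoring
    with Wilcoxon signed-rank anomaly detection.  A synthetic multi-site
    mpMRI phantom generator with injectable annotation corruption makes
    every stage testable without access to real patient data; real
    BraTS-format NIfTI data can be consumed through the same readers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
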