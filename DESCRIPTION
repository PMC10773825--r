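Package: poolunetr
Title: Pooling-Mixer U-Shaped Transformer Networks for 3D Medical Image
    Segmentation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds, trains and evaluates U-shaped hierarchical 3D
    segmentation networks in which the windowed self-attention token mixer
    of a Swin-UNETR-style encoder is replaced by a parameter-free spatial
    average-pooling operator, optionally augmented with
    squeeze-and-excitation channel recalibration.  Provides the soft Dice
    loss and Dice metric, overlapping tumor-region construction for
    multi-modal brain MRI labels, NIfTI volume input/output, dataset
    manifests, five-fold cross-validation splits, seedable synthetic
    phantom generators for both dataset regimes, a seeded training loop
    with sliding-window inference, and an exact per-component
    trainable-parameter accounting harness that checksums built networks
    against reference totals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
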