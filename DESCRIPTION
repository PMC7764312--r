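Package: sauseg
Title: Split-Attention Nested U-Net Segmentation of 3D Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pure CPU implementation of a three-dimensional split-attention
    nested U-Net for multi-label brain MRI segmentation, together with the
    surrounding pipeline: NIfTI input/output, histogram-landmark intensity
    standardization, stochastic training-time augmentation (noise, bias field,
    affine, elastic), two-step training with auxiliary labels followed by
    fine-tuning on manual labels, patch-based whole-volume inference with
    OR-logical label fusion, and evaluation metrics (Dice overlap, average
    symmetric surface distance, structure volumes, and test-retest
    coefficients of variation). A deterministic synthetic phantom generator
    produces T1-like volumes so the entire pipeline can be exercised and
    tested without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
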