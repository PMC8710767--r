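Package: localbrainage
Title: Voxelwise Brain-Age Prediction with a 3D Regression U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Local (voxel-level) brain-age estimation from grey- and
    white-matter volume maps. Implements a 3D regression U-Net that maps
    overlapping 52^3 two-channel tissue blocks to 12^3 blocks of voxelwise
    predicted age, trained with a composite absolute-error loss with
    decaying auxiliary block-level terms; block planning, extraction and
    stitching of whole-brain prediction maps; per-voxel age-bin and global
    linear bias adjustment of brain-age deltas; reliability (ICC) mapping
    and group-comparison statistics (Welch's t, Cohen's d, Bonferroni);
    and a synthetic brain-phantom generator with a known, spatially
    varying age effect for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
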