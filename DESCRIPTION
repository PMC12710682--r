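Package: bhvsi
Title: Breath-Hold Venous Vessel Size Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Toolkit for venous vessel size imaging (VSI) from breath-hold
    BOLD fMRI. Provides a Monte-Carlo simulator of gradient-echo and
    spin-echo transverse relaxation around random cylinder networks, the
    resulting vessel-size-index calibration (robust sixth-order fit of
    radius on ln q), a dual-echo block-design mapping pipeline that turns
    SAGE breath-hold runs into voxelwise Delta-R2*, Delta-R2, q and mean
    vessel radius maps, and a synthetic dual-echo phantom generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
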