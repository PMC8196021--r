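Package: netdisrupt
Title: Functional Connectivity Disruption Analysis for Two-Group fMRI Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects functional connectivity disruptions between two small
    cohorts (e.g. healthy controls versus an injury group) from resting-state
    and block-design task fMRI. Implements group sparse dictionary learning
    with dual regression and group independent component analysis with
    back-reconstruction to obtain per-subject spatial activation maps,
    atlas-referenced Pearson spatial correlation and mean-ratio statistics
    with Welch group tests under a dual-metric significance rule, and an
    exhaustive voxelwise two-group permutation test with per-region
    percentages of significantly decreasing and increasing voxels. Ships a
    synthetic 4D BOLD phantom generator with a seven-network label atlas so
    the whole pipeline is testable end to end without any acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
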