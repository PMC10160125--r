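Package: longplsc
Title: Longitudinal Partial Least Squares Correlation for Seed-Based
    Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for multivariate analysis of seed-based
    resting-state functional connectivity in mixed cross-sectional and
    longitudinal cohorts. Builds mutually exclusive region-of-interest
    masks from probabilistic atlases, computes framewise displacement and
    motion-censored seed-to-voxel Pearson connectivity maps, encodes
    group, cross-sectional age, longitudinal age and their interactions
    into a standardized design matrix, residualizes voxelwise confounds,
    and performs partial least squares correlation (PLS-C) with
    subject-level permutation testing of singular values and subject-level
    bootstrap stability (bootstrap ratios). A synthetic-data module
    generates cohorts, feature matrices and toy 4D volumes with known
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
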