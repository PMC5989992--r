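Package: lcpr
Title: Local Connectome Phenotype Mapping via Sparse Principal Components
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for mapping subject attributes onto local connectome
    fingerprints: high-dimensional per-subject vectors of fiber-wise
    diffusion-density values sampled throughout cerebral white matter.
    Implements the LASSO-PCR pipeline (economical singular value
    decomposition of the fingerprint matrix, L1-penalized regression of a
    response on component scores plus intracranial volume, confound
    truncation, and back-projection of coefficients into fiber space as
    phenotype weight maps), together with five-fold cross-validated
    evaluation, permutation tests, bootstrap confidence intervals,
    false-discovery-rate control, pairwise fingerprint-similarity
    summaries, and voxel-space map export. A synthetic cohort generator
    with planted low-rank structure and known effect directions makes
    every stage testable without access to restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
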