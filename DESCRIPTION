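Package: diffusionMKL
Title: Multi-Scale Diffusion Kernel Learning for Brain Structure-Function
    Coupling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts resting-state functional connectivity from structural
    connectomes by learning a sparse linear combination of multi-scale graph
    diffusion kernels. Structural connectivity matrices are turned into graph
    Laplacians, a bank of heat kernels at log-spaced diffusion scales is built
    from the spectral decomposition, and scale-specific co-activation matrices
    are estimated across a training cohort by column-wise LASSO. Includes a
    single-diffusion-kernel baseline, a reduced dynamic-mean-field simulator
    with a Balloon-Windkessel BOLD forward model, cross-validation and
    robustness batteries (connection thresholding, structural perturbation,
    co-activation swap and row-permutation nulls, seed-based correlation
    maps), and a synthetic cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    Matrix,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
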