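Package: cbma
Title: Coordinate-Based Meta-Analysis of Neuroimaging Foci with ALE and
    Latent Factor Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for coordinate-based meta-analysis of functional
    neuroimaging results. Implements the revised activation likelihood
    estimation (ALE) algorithm with sample-size-scaled Gaussian kernels,
    modeled-activation maps, an analytic random-association null
    distribution, and permutation-based cluster-level family-wise error
    control; latent Dirichlet allocation over study-by-voxel documents
    fitted by zeroth-order collapsed variational Bayes with BIC model
    selection; readers for Sleuth-style and CSV coordinate tables with
    Talairach-to-MNI conversion; NIfTI volume input/output; and a
    synthetic-corpus generator with planted convergence clusters for
    method validation.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
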