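Package: tripnet
Title: Latent Mechanism Projection for Families of Causal Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Explains families of condition-specific weighted causal graphs
    through a small number of latent mechanisms. Each observed graph W is
    summarized by a low-dimensional latent interaction matrix U = C'WC
    through an orthonormal projection C, and the projection is learned
    jointly with a nonlinear predictor of per-condition indicators by
    minimizing a prediction loss plus a truncated-reconstruction penalty
    (TRIP). Includes the generative direction (synthesizing DAG-constrained
    graphs from fixed mechanisms via an acyclicity-penalized augmented
    Lagrangian), Stiefel-manifold optimization through an SVD
    parameterization, bilinear-surrogate interpretation of the learned
    predictor, reconstruction-only and vector-space baselines, and seeded
    synthetic benchmark generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
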