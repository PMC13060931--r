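Package: smds
Title: Stiefel Manifold Dynamical Systems for Tracking Representational Drift
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Latent linear-Gaussian dynamical systems for trial-structured
    neural population recordings in which the orthonormal emission matrix is
    allowed to move smoothly across trials on the Stiefel manifold, capturing
    within-session representational drift while the latent dynamics stay
    fixed. Provides the drifting-emission model with variational
    expectation-maximization inference (exact Kalman smoothing over states,
    extended Kalman smoothing over subspace displacements), a standard linear
    dynamical system baseline with closed-form EM, Stiefel/Grassmann geometry
    utilities (Cayley retraction, principal angles, Grassmann distances),
    drift quantification reports, held-out likelihood model selection, and a
    simulator for synthetic drifting-subspace experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Matrix,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
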