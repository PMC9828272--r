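Package: crwgp
Title: Hierarchical Gaussian Process Models of Spatially Varying Animal
    Movement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a two-layer hierarchical Gaussian process model to GPS
    trajectories from multiple individuals. The top layer is a
    continuous-time correlated random walk (integrated Ornstein-Uhlenbeck
    velocity process) whose directional-persistence timescale and velocity
    variance vary over space through a non-stationary covariance kernel.
    The bottom layer places sparse Gaussian process priors, anchored at an
    inducing grid, on the log-scale spatial fields of both parameters,
    optionally with environmental covariates in the mean. Inference is by
    stochastic variational optimisation with analytic gradients. Includes
    a correlated-random-walk simulator over warped-sine environments with
    periodic boundaries for validation of parameter recovery, posterior
    field mapping, and covariate response summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
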