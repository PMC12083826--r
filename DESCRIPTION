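Package: adaptivecest
Title: Adaptive Bayesian Design of CEST NMR Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-loop, mutual-information-driven selection of irradiation
    conditions for 15N chemical exchange saturation transfer (CEST) NMR
    experiments on proteins. Implements a two-state Bloch-McConnell forward
    model with an exact matrix-exponential propagator, an eigenvalue R1rho
    route and a fast refined-seed approximation; per-residue Bayesian
    inference of exchange parameters by adaptive Metropolis MCMC under the
    linear/log-uniform priors of the CEST literature; a sequential optimal
    experimental design engine that scores candidate saturation conditions
    by the mutual information between predicted intensities and model
    parameters; a virtual spectrometer for simulation studies; and
    conventional evenly-spaced schedules for head-to-head comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
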