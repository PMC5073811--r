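Package: evidencer
Title: Posterior Sampling and Marginal-Likelihood Estimation for Computational Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three families of sampling algorithms for Bayesian analysis of
    simulation-based computational models: parallel-tempered Markov chain Monte
    Carlo with adaptive proposals, feedback-optimized temperature ladders,
    automated parameter blocking and thermodynamic-integration evidence
    estimation; sequential Monte Carlo with an automated temperature schedule,
    systematic resampling and MCMC or kernel-density move kernels; and nested
    sampling with likelihood-constrained MCMC, single-ellipsoid and
    multi-ellipsoid replacement strategies. Every run returns posterior samples
    together with a marginal-likelihood (evidence) estimate and an error bound.
    Models are supplied as likelihood plugins over a named parameter vector with
    priors declared in a small XML dialect. Built-in benchmarks include the
    analytically tractable Gaussian-shells likelihood and a kinetic
    ordinary-differential-equation demo with a synthetic time-course generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    xml2,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
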