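Package: tracermix
Title: Bayesian Tracer Mixing Models with Covariates
Version: 0.1.0
Authors@R:
    person("tracermix", "developers", email = "tracermix@example.org",
           role = c("aut", "cre"))
Description: Estimates proportional source contributions to mixtures
    (e.g., consumer diets) from tracer data such as stable isotope or
    fatty-acid profiles. Implements the family of Bayesian mixing models
    with selectable mixture error structures (residual, process, and
    process-by-multiplicative), three source-data treatments (raw samples,
    summary statistics, fixed), Dirichlet priors on source proportions,
    and fixed/random covariate effects on an isometric log-ratio (ILR)
    scale. Includes an adaptive Metropolis-within-Gibbs sampler, exhaustive
    grid-posterior oracles for tiny models, convergence diagnostics,
    post-hoc source combining, specialization indices, mixing-polygon
    diagnostics, WAIC and PSIS-LOO model comparison, a synthetic-data
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
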