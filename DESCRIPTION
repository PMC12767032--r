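Package: betabym
Title: Bayesian Beta Regression Disease Mapping with BYM Spatial Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Small-area estimation of bounded prevalence outcomes with a beta
    likelihood in mean-precision form, a logit link, and Besag-York-Mollie
    (BYM) random effects: an intrinsic conditional autoregressive (ICAR)
    structured spatial term plus an unstructured Gaussian term. Fits the model
    by adaptive Metropolis-within-Gibbs sampling with convergence diagnostics,
    and turns posterior draws into per-area predicted prevalence with 95%
    credible intervals, exceedance probabilities for policy thresholds,
    covariate significance flags, leave-one-out cross-validation, and static
    plus interactive choropleth maps. Includes a synthetic-data generator
    that reproduces the assumed statistical structure (contiguity graph,
    spatially smooth covariates, beta-distributed proportions) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    coda,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
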