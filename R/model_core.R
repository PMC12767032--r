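#' Logit link and its inverse
#'
#' The link g(mu) = log(mu / (1 - mu)) mapping (0,1) to the real line, and
#' the numerically stable inverse that never underflows to exactly 0 or 1
#' for |x| up to ~700.
#'
#' @param p proportion(s) strictly in (0,1).
#' @param x real value(s).
#' @return `logit`: real values; `inv_logit`: proportions in (0,1).
#' @export
logit <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop_domain("domain error: logit requires p in (0,1)")
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

#' Beta log density in mean-precision form
#'
#' Log density of Beta(a, b) with a = mu * phi, b = (1 - mu) * phi, so that
#' E(Y) = mu and Var(Y) = mu (1 - mu) / (1 + phi). This is the standard
#' beta-regression parameterization: phi acts as a precision, larger values
#' concentrating the distribution around its mean.
#'
#' @param y observed proportion(s) strictly in (0,1).
#' @param mu mean(s) in (0,1).
#' @param phi precision(s) > 0.
#' @return Log density value(s).
#' @export
beta_log_density <- function(y, mu, phi) {
  if (any(!is.finite(y) | y <= 0 | y >= 1))
    stop_domain("domain error: y must be strictly in (0,1)")
  if (any(mu <= 0 | mu >= 1) || any(phi <= 0))
    stop_domain("domain error: need mu in (0,1) and phi > 0")
  dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

#' ICAR log density (pairwise-difference kernel)
#'
#' Log density of the intrinsic CAR prior on the structured spatial effect,
#' up to an additive constant:
#' \deqn{-\frac{1}{2\sigma_w^2}\sum_{i \sim j}(w_i - w_j)^2
#'       - \frac{n - c}{2}\log \sigma_w^2,}
#' each undirected edge counted once; n - c is the rank of the structure
#' matrix (c connected components). Equivalent to the degenerate Gaussian
#' with precision Q / sigma_w^2 on the per-component sum-to-zero subspace.
#' Isolated areas contribute nothing and must have w = 0.
#'
#' @param w effect vector satisfying the per-component sum-to-zero
#'   constraint within `tol`.
#' @param graph a `spatial_graph`.
#' @param sigma_w2 structured-effect variance (> 0).
#' @param tol constraint tolerance.
#' @return Log density up to a constant.
#' @export
icar_log_density <- function(w, graph, sigma_w2, tol = 1e-8) {
  stopifnot(inherits(graph, "spatial_graph"))
  if (length(w) != graph$n) stop_domain("w must have one entry per area")
  if (sigma_w2 <= 0) stop_domain("sigma_w2 must be positive")
  comp_sums <- tapply(w, graph$component_labels, sum)
  if (any(abs(comp_sums) > tol))
    stop_domain("sum-to-zero constraint violated (max |component sum| = ",
                format(max(abs(comp_sums))), ")")
  e <- graph$edges
  ss <- if (nrow(e)) sum((w[e[, 1]] - w[e[, 2]])^2) else 0
  n_eff <- graph$n - max(graph$component_labels)
  -ss / (2 * sigma_w2) - (n_eff / 2) * log(sigma_w2)
}

#' Prior specification
#'
#' Defaults emulate the flat/vague priors common in disease-mapping
#' software: regression coefficients Normal(0, sd 31.62) (precision 0.001),
#' a flat intercept, Gamma(1, 5e-5) priors on the precisions of both random
#' effects (i.e. log-gamma on the log precisions), and Gamma(1, 0.01) on
#' the beta precision phi. All overridable.
#'
#' @param beta_sd prior SD for each regression coefficient.
#' @param beta0_sd prior SD for the intercept; `Inf` means flat.
#' @param precision_prior `(shape, rate)` of the Gamma prior on
#'   1/sigma_w^2 and 1/sigma_v^2.
#' @param phi_prior `(shape, rate)` of the Gamma prior on phi.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(beta_sd = 31.62, beta0_sd = Inf,
                       precision_prior = c(shape = 1, rate = 5e-5),
                       phi_prior = c(shape = 1, rate = 0.01)) {
  stopifnot(beta_sd > 0, beta0_sd > 0, all(precision_prior > 0),
            all(phi_prior > 0))
  structure(list(beta_sd = beta_sd, beta0_sd = beta0_sd,
                 precision_prior = unname(precision_prior),
                 phi_prior = unname(phi_prior)),
            class = "prior_spec")
}

# log prior of a variance sigma2 when 1/sigma2 ~ Gamma(a, b):
# p(sigma2) = dgamma(1/sigma2; a, b) / sigma2^2
log_prior_variance <- function(sigma2, a, b) {
  dgamma(1 / sigma2, shape = a, rate = b, log = TRUE) - 2 * log(sigma2)
}

#' Parameter state constructor
#'
#' One point in the model's parameter space. The structured effect `w` must
#' sum to zero within every connected component (the identifiability
#' constraint against the intrinsic ICAR's flat level).
#'
#' @param beta0 intercept.
#' @param beta covariate coefficient vector (length k, possibly 0).
#' @param w structured spatial effect (length n).
#' @param v unstructured effect (length n).
#' @param sigma_w2,sigma_v2 variances (> 0).
#' @param phi beta precision (> 0).
#' @return A `parameter_state` list.
#' @export
parameter_state <- function(beta0, beta, w, v, sigma_w2, sigma_v2, phi) {
  stopifnot(sigma_w2 > 0, sigma_v2 > 0, phi > 0, length(w) == length(v))
  structure(list(beta0 = beta0, beta = as.numeric(beta), w = as.numeric(w),
                 v = as.numeric(v), sigma_w2 = sigma_w2,
                 sigma_v2 = sigma_v2, phi = phi),
            class = "parameter_state")
}

#' Linear predictor and fitted means
#'
#' eta_i = beta0 + x_i' beta + w_i + v_i and mu_i = inv_logit(eta_i).
#'
#' @param state a `parameter_state`.
#' @param table a `county_table` aligned with `state`.
#' @return List with `eta` and `mu` (both length n).
#' @export
linear_predictor <- function(state, table) {
  eta <- state$beta0 + as.vector(table$X %*% state$beta) + state$w + state$v
  list(eta = eta, mu = inv_logit(eta))
}

#' Joint log posterior (up to a constant)
#'
#' Beta likelihood + ICAR kernel on w + i.i.d. Gaussian on v + priors on
#' the intercept, coefficients, both variances and phi. This is the
#' reference density the MCMC sampler targets; it is kept in plain R so it
#' can be audited and differentiated numerically in tests.
#'
#' @param state a `parameter_state`.
#' @param table a `county_table`.
#' @param graph a `spatial_graph` aligned with `table`.
#' @param priors a [prior_spec()].
#' @return Log posterior density up to a state-independent constant.
#' @export
log_posterior <- function(state, table, graph, priors = prior_spec()) {
  n <- table$n_areas
  if (graph$n != n || length(state$w) != n)
    stop_domain("integrity error: table, graph and state dimensions differ")
  if (length(state$beta) != ncol(table$X))
    stop_domain("integrity error: beta length != number of covariates")
  lp <- linear_predictor(state, table)
  ll <- sum(beta_log_density(table$y, lp$mu, state$phi))
  lw <- icar_log_density(state$w, graph, state$sigma_w2)
  lv <- sum(dnorm(state$v, 0, sqrt(state$sigma_v2), log = TRUE))
  pr <- 0
  if (is.finite(priors$beta0_sd))
    pr <- pr + dnorm(state$beta0, 0, priors$beta0_sd, log = TRUE)
  if (length(state$beta))
    pr <- pr + sum(dnorm(state$beta, 0, priors$beta_sd, log = TRUE))
  a <- priors$precision_prior[1]; b <- priors$precision_prior[2]
  pr <- pr + log_prior_variance(state$sigma_w2, a, b)
  pr <- pr + log_prior_variance(state$sigma_v2, a, b)
  pr <- pr + dgamma(state$phi, shape = priors$phi_prior[1],
                    rate = priors$phi_prior[2], log = TRUE)
  ll + lw + lv + pr
}
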