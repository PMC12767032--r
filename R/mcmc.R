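#' MCMC configuration
#'
#' @param n_chains number of chains (>= 2 for diagnostics).
#' @param n_iterations total iterations per chain.
#' @param n_burnin discarded prefix (< n_iterations).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer RNG seed; the full run is reproducible from it.
#' @param adapt_until iteration at which proposal adaptation stops
#'   (<= n_burnin so the retained chain is Markovian); defaults to n_burnin.
#' @param target_accept target acceptance rate for the scalar random-walk
#'   updates (0.44, the standard single-dimension optimum).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 4, n_iterations = 20000,
                        n_burnin = 10000, thin = 5, seed = 1,
                        adapt_until = NULL, target_accept = 0.44) {
  adapt_until <- adapt_until %||% n_burnin
  stopifnot(n_chains >= 1, n_burnin < n_iterations, adapt_until <= n_burnin,
            thin >= 1, target_accept > 0, target_accept < 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_until = as.integer(adapt_until),
                 target_accept = target_accept),
            class = "mcmc_config")
}

#' Run the beta-BYM MCMC sampler
#'
#' Adaptive Metropolis-within-Gibbs: scalar random-walk updates for the
#' intercept, each coefficient, log sigma_w^2, log sigma_v^2 and log phi;
#' single-site updates for each w_i and v_i on alternating sweeps (a
#' standard mitigation of BYM random-walk stickiness), with w re-centred to
#' the per-component sum-to-zero constraint after every w sweep. Proposal
#' scales adapt by Robbins-Monro during burn-in only. Chains start
#' overdispersed: the intercept at logit(mean y) plus jitter, coefficients
#' jittered around 0, random effects at 0, variances log-uniform on
#' [0.005, 0.5], and phi around a method-of-moments estimate.
#'
#' Deterministic given `config$seed` and the iteration schedule.
#'
#' @param table a `county_table`.
#' @param graph a `spatial_graph` aligned with `table`.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param include_v include the unstructured effect v (TRUE by default).
#' @param fixed optional named list pinning `phi`, `sigma_w2` and/or
#'   `sigma_v2` at fixed values (used for reduced models).
#' @param holdout integer indices of areas excluded from the likelihood
#'   (their parameters are still sampled from the prior conditional).
#' @param likelihood set FALSE to sample from the prior only (testing).
#' @return A `bym_samples` object: `draws` (matrix, one row per retained
#'   draw, named columns `beta0`, `beta[...]`, `w[i]`, `v[i]`, `sigma_w2`,
#'   `sigma_v2`, `phi`, `mu[i]`), `chain` ids, `config`, `acceptance`
#'   per chain, plus the `table`, `graph` and `priors` used.
#' @export
run_sampler <- function(table, graph, priors = prior_spec(),
                        config = mcmc_config(), include_v = TRUE,
                        fixed = list(), holdout = integer(0),
                        likelihood = TRUE) {
  stopifnot(inherits(table, "county_table"), inherits(graph, "spatial_graph"))
  if (graph$n != table$n_areas)
    stop_domain("integrity error: graph and table sizes differ")
  n <- table$n_areas
  k <- ncol(table$X)
  mask <- rep(TRUE, n)
  mask[holdout] <- FALSE
  has_edges <- nrow(graph$edges) > 0

  nb0 <- lapply(graph$neighbors, function(v) as.integer(v - 1L))
  edges0 <- graph$edges - 1L
  if (!nrow(edges0)) edges0 <- matrix(integer(0), ncol = 2)
  comp0 <- as.integer(graph$component_labels - 1L)

  ybar <- mean(table$y)
  mom_phi <- max(2, mean(table$y * (1 - table$y)) / max(var(table$y), 1e-6) - 1)

  # centred covariates: the chain samples beta0c = beta0 + xbar' beta, which
  # decorrelates the intercept from the coefficients; draws are mapped back
  xbar <- if (k) colMeans(table$X) else numeric(0)
  Xc <- if (k) sweep(table$X, 2, xbar) else table$X

  set.seed(config$seed)
  chains <- vector("list", config$n_chains)
  accepts <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    beta0_init <- logit(ybar) + rnorm(1, 0, 0.3)
    beta_init <- if (k) rnorm(k, 0, 0.01) else numeric(0)
    sw2_init <- fixed$sigma_w2 %||% exp(runif(1, log(0.005), log(0.5)))
    sv2_init <- fixed$sigma_v2 %||% exp(runif(1, log(0.005), log(0.5)))
    phi_init <- fixed$phi %||% (mom_phi * exp(runif(1, -1, 1)))
    st <- tryCatch(
      log_posterior(parameter_state(beta0_init, beta_init, rep(0, n),
                                    rep(0, n), sw2_init, sv2_init, phi_init),
                    table, graph, priors),
      error = function(e) NA_real_)
    if (!is.finite(st) && likelihood && !length(holdout))
      stop_domain("initialization error: non-finite log posterior at the ",
                  "chain ", ch, " starting state (check y, covariates, phi)")
    res <- .bym_chain(
      table$y, Xc, nb0, edges0, comp0, mask,
      beta0_init, beta_init, rep(0, n), rep(0, n),
      sw2_init, sv2_init, phi_init,
      priors$beta_sd, priors$beta0_sd,
      priors$precision_prior[1], priors$precision_prior[2],
      priors$phi_prior[1], priors$phi_prior[2],
      config$n_iterations, config$n_burnin, config$thin, config$adapt_until,
      config$target_accept,
      include_v,
      is.null(fixed$sigma_w2) && has_edges,
      is.null(fixed$sigma_v2) && include_v,
      is.null(fixed$phi),
      likelihood)
    draws_ch <- res$draws
    if (k)  # beta0 = beta0c - xbar' beta
      draws_ch[, 1] <- draws_ch[, 1] -
        as.vector(draws_ch[, 1 + seq_len(k), drop = FALSE] %*% xbar)
    chains[[ch]] <- draws_ch
    accepts[[ch]] <- res$acceptance
  }
  draws <- do.call(rbind, chains)
  cov_names <- if (k) colnames(table$X) else character(0)
  colnames(draws) <- c(
    "beta0",
    if (k) paste0("beta[", cov_names, "]"),
    paste0("w[", seq_len(n), "]"), paste0("v[", seq_len(n), "]"),
    "sigma_w2", "sigma_v2", "phi",
    paste0("mu[", seq_len(n), "]"))
  chain_id <- rep(seq_len(config$n_chains),
                  each = nrow(chains[[1]]))
  structure(list(draws = draws, chain = chain_id, config = config,
                 acceptance = accepts, table = table, graph = graph,
                 priors = priors, include_v = include_v, fixed = fixed,
                 holdout = holdout),
            class = "bym_samples")
}

#' @export
print.bym_samples <- function(x, ...) {
  cat("bym_samples:", nrow(x$draws), "retained draws (",
      x$config$n_chains, "chains ),", ncol(x$draws), "quantities\n")
  invisible(x)
}

#' Persist retained draws as columnar CSV
#'
#' One row per retained draw, a `chain` column plus one column per scalar.
#'
#' @param samples a `bym_samples`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(samples, path) {
  df <- data.frame(chain = samples$chain, samples$draws, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- diagnostics ------------------------------------------------------------

# split chains in half; x is a draws x chains matrix
split_chains <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  cbind(m[seq_len(half), , drop = FALSE],
        m[(n - half + 1):n, , drop = FALSE])
}

rank_normalize <- function(m) {
  z <- qnorm((rank(as.vector(m)) - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow = nrow(m))
}

rhat_matrix <- function(m) {
  # m: draws x chains (already split); basic split-Rhat
  n <- nrow(m); mchains <- ncol(m)
  if (n < 2 || mchains < 2) return(NA_real_)
  means <- colMeans(m)
  vars <- apply(m, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_matrix <- function(m) {
  # rank-normalized bulk ESS via Geyer's initial monotone sequence
  n <- nrow(m); mchains <- ncol(m)
  if (n < 3) return(NA_real_)
  z <- rank_normalize(m)
  means <- colMeans(z)
  vars <- apply(z, 2, var)
  W <- mean(vars)
  B <- if (mchains > 1) n * var(means) else 0
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus <= 0 || W <= 0) return(n * mchains)
  # chain autocovariances via FFT
  acov <- sapply(seq_len(mchains), function(ch) {
    x <- z[, ch] - means[ch]
    npad <- 2^ceiling(log2(2 * n))
    f <- fft(c(x, rep(0, npad - n)))
    ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / npad
    ac / n * (n / (n - 1))
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # rho[t+1] = lag-t correlation
  # Geyer initial monotone positive sequence over pairs (lag 2k, 2k+1)
  P <- numeric(0)
  for (kk in 0:(floor((n - 1) / 2) - 1)) {
    p <- rho[2 * kk + 1] + rho[2 * kk + 2]
    if (!is.finite(p) || p <= 0) break
    P <- c(P, p)
  }
  if (length(P) > 1) P <- cummin(P)
  tau <- max(-1 + 2 * sum(P), 1)
  n * mchains / tau
}

#' Convergence diagnostics
#'
#' Split-R-hat and rank-normalized effective sample size for every sampled
#' scalar (standard rank-normalized formulas), plus per-block acceptance
#' rates. The run is flagged converged when every monitored R-hat is below
#' 1.05.
#'
#' @param samples a `bym_samples` with >= 2 chains and >= 100 retained
#'   draws per chain.
#' @param params optional character vector restricting which columns are
#'   monitored; defaults to every sampled scalar (mu columns excluded).
#' @return A `diagnostics_report`: data.frame `summary` (param, rhat, ess),
#'   `acceptance_rates`, `converged`.
#' @export
diagnostics <- function(samples, params = NULL) {
  stopifnot(inherits(samples, "bym_samples"))
  n_chains <- samples$config$n_chains
  if (n_chains < 2)
    stop_domain("diagnostics require at least 2 chains")
  per_chain <- nrow(samples$draws) / n_chains
  if (per_chain < 100)
    stop_domain("diagnostics require >= 100 retained draws per chain")
  cols <- params %||% grep("^mu\\[", colnames(samples$draws),
                           value = TRUE, invert = TRUE)
  # drop constants (e.g. fixed parameters, pinned w of isolated areas)
  keep <- vapply(cols, function(cn)
    var(samples$draws[, cn]) > 1e-14, logical(1))
  cols <- cols[keep]
  stats <- t(vapply(cols, function(cn) {
    m <- matrix(samples$draws[, cn], ncol = n_chains)
    c(rhat = rhat_matrix(rank_normalize(split_chains(m))),
      ess = ess_matrix(m))
  }, c(rhat = 0, ess = 0)))
  summary <- data.frame(param = cols, rhat = stats[, "rhat"],
                        ess = stats[, "ess"], row.names = NULL,
                        stringsAsFactors = FALSE)
  acc <- samples$acceptance[[1]]
  structure(list(summary = summary,
                 acceptance_rates = acc,
                 converged = all(is.finite(summary$rhat)) &&
                   all(summary$rhat < 1.05)),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("MCMC diagnostics: converged =", x$converged, "\n")
  cat("  max R-hat:", format(max(x$summary$rhat), digits = 4),
      " min ESS:", format(min(x$summary$ess), digits = 4), "\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Empirical mean, SD and central 95% credible interval per scalar, pooled
#' across chains. Interval endpoints use the inverse empirical CDF
#' (order-statistic) quantile so they are always attained draw values.
#'
#' @param samples a `bym_samples` (or plain draws matrix).
#' @param params optional subset of column names.
#' @return data.frame with columns param, mean, sd, lower, upper.
#' @export
summarize_posterior <- function(samples, params = NULL) {
  draws <- if (inherits(samples, "bym_samples")) samples$draws else samples
  if (!nrow(draws)) stop_domain("no draws to summarize")
  cols <- params %||% colnames(draws)
  out <- t(vapply(cols, function(cn) {
    x <- draws[, cn]
    q <- unname(quantile(x, c(0.025, 0.975), type = 1))
    c(mean = mean(x), sd = sd(x), lower = q[1], upper = q[2])
  }, c(mean = 0, sd = 0, lower = 0, upper = 0)))
  data.frame(param = cols, out, row.names = NULL, stringsAsFactors = FALSE)
}
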