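mu_draws <- function(samples) {
  cols <- grep("^mu\\[", colnames(samples$draws), value = TRUE)
  samples$draws[, cols, drop = FALSE]
}

#' Per-area posterior predictions
#'
#' Posterior mean, SD and central 95% credible interval of the fitted
#' prevalence mu_i per area, alongside the observed proportion.
#'
#' @param samples a `bym_samples`.
#' @return data.frame with columns area_id, area_name, observed, predicted,
#'   sd, lower, upper (all on the proportion scale).
#' @export
county_predictions <- function(samples) {
  stopifnot(inherits(samples, "bym_samples"))
  mu <- mu_draws(samples)
  q <- apply(mu, 2, quantile, probs = c(0.025, 0.975), type = 1)
  data.frame(area_id = samples$table$area_id,
             area_name = samples$table$area_name,
             observed = samples$table$y,
             predicted = colMeans(mu),
             sd = apply(mu, 2, sd),
             lower = q[1, ], upper = q[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exceedance probabilities
#'
#' Posterior probability that each area's prevalence exceeds a policy
#' threshold: the fraction of retained draws with mu_i > t. Thresholds are
#' configurable; the conventional defaults for high-burden screening are
#' 0.70 and 0.75.
#'
#' @param samples a `bym_samples`.
#' @param thresholds numeric vector of thresholds, all strictly in (0,1).
#' @return data.frame: area_id plus one `exceed_<t>` column per threshold.
#' @export
exceedance_probabilities <- function(samples, thresholds = c(0.70, 0.75)) {
  stopifnot(inherits(samples, "bym_samples"))
  if (any(thresholds <= 0 | thresholds >= 1))
    stop_domain("thresholds must be strictly in (0,1)")
  mu <- mu_draws(samples)
  out <- data.frame(area_id = samples$table$area_id,
                    stringsAsFactors = FALSE)
  for (t in thresholds)
    out[[sprintf("exceed_%g", t)]] <- colMeans(mu > t)
  out
}

#' Covariate significance flags
#'
#' A covariate is declared significant when its central 95% credible
#' interval excludes zero (both bounds share a sign).
#'
#' @param x a `bym_samples` or a [summarize_posterior()] data.frame
#'   containing the `beta[...]` rows.
#' @return data.frame: covariate, mean, lower, upper, significant.
#' @export
significant_covariates <- function(x) {
  summ <- if (inherits(x, "bym_samples")) {
    cols <- grep("^beta\\[", colnames(x$draws), value = TRUE)
    summarize_posterior(x, cols)
  } else {
    x[grepl("^beta\\[", x$param), , drop = FALSE]
  }
  if (!nrow(summ)) stop_domain("no covariate coefficients found")
  data.frame(covariate = sub("^beta\\[(.*)\\]$", "\\1", summ$param),
             mean = summ$mean, lower = summ$lower, upper = summ$upper,
             significant = summ$lower * summ$upper > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overall prevalence summary
#'
#' Unweighted arithmetic mean, minimum and maximum across areas, for both
#' the observed and the predicted prevalence columns.
#'
#' @param predictions output of [county_predictions()].
#' @return list with `observed` and `predicted`, each `c(mean, min, max)`.
#' @export
overall_summary <- function(predictions) {
  if (!nrow(predictions)) stop_domain("empty prediction table")
  s <- function(x) c(mean = mean(x), min = min(x), max = max(x))
  list(observed = s(predictions$observed),
       predicted = s(predictions$predicted))
}

#' Fit the beta-BYM model end to end
#'
#' Convenience wrapper: runs the sampler, computes diagnostics, per-area
#' predictions, exceedance probabilities, covariate significance and the
#' overall summary.
#'
#' @inheritParams run_sampler
#' @param thresholds exceedance thresholds (proportions).
#' @return A `bym_fit`: list with `samples`, `diagnostics`, `predictions`,
#'   `exceedance`, `covariates` (NULL when the model has none), `overall`.
#' @export
fit_bym <- function(table, graph, priors = prior_spec(),
                    config = mcmc_config(), thresholds = c(0.70, 0.75),
                    include_v = TRUE) {
  samples <- run_sampler(table, graph, priors, config, include_v = include_v)
  preds <- county_predictions(samples)
  structure(list(
    samples = samples,
    diagnostics = if (config$n_chains >= 2) diagnostics(samples),
    predictions = preds,
    exceedance = exceedance_probabilities(samples, thresholds),
    covariates = if (ncol(table$X)) significant_covariates(samples),
    overall = overall_summary(preds)),
    class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  ov <- x$overall
  cat("beta-BYM fit over", nrow(x$predictions), "areas\n")
  cat(sprintf("  observed prevalence:  mean %.1f%%, range %.1f%%-%.1f%%\n",
              100 * ov$observed["mean"], 100 * ov$observed["min"],
              100 * ov$observed["max"]))
  cat(sprintf("  predicted prevalence: mean %.1f%%, range %.1f%%-%.1f%%\n",
              100 * ov$predicted["mean"], 100 * ov$predicted["min"],
              100 * ov$predicted["max"]))
  if (!is.null(x$covariates)) {
    sig <- x$covariates[x$covariates$significant, , drop = FALSE]
    cat("  significant covariates:",
        if (nrow(sig)) paste(sig$covariate, collapse = ", ") else "none",
        "\n")
  }
  if (!is.null(x$diagnostics))
    cat("  converged:", x$diagnostics$converged, "\n")
  invisible(x)
}

#' Export a fit as CSV and JSON
#'
#' Writes the per-area table (one row per area: observation, prediction,
#' CrI, exceedance) as CSV, and the covariate + overall summaries as a
#' JSON block.
#'
#' @param fit a `bym_fit`.
#' @param csv_path,json_path output paths (NULL to skip either).
#' @return Invisibly, the per-area data.frame.
#' @export
write_fit <- function(fit, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(fit, "bym_fit"))
  tab <- merge(fit$predictions, fit$exceedance, by = "area_id", sort = FALSE)
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(overall = lapply(fit$overall, as.list),
           covariates = fit$covariates,
           converged = if (!is.null(fit$diagnostics))
             fit$diagnostics$converged),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tab)
}

#' Leave-one-out cross-validation
#'
#' For each (selected) area, refits the model with that area's outcome held
#' out of the likelihood and predicts its prevalence as
#' `inv_logit(beta0 + x_i' beta + w_i*)`, where `w_i*` is the ICAR
#' conditional mean of the held-out area given its neighbours' sampled
#' structured effects (the neighbour average per draw; 0 for isolated
#' areas). The unstructured effect is set to its prior mean 0. Predictive
#' power is summarized by the Pearson correlation between observed and
#' held-out predicted prevalence.
#'
#' @inheritParams run_sampler
#' @param folds optional integer vector of area indices to hold out
#'   (default: every area). Subsampling folds is the fast mode; the
#'   correlation is then computed over the subsample.
#' @return A `validation_result`: data.frame `predictions` (area_id,
#'   observed, predicted), `r`, `p_value`, `n_folds`.
#' @export
loocv_validate <- function(table, graph, priors = prior_spec(),
                           config = mcmc_config(), folds = NULL,
                           include_v = TRUE) {
  n <- table$n_areas
  if (n < 5) stop_domain("cross-validation needs at least 5 areas")
  folds <- folds %||% seq_len(n)
  preds <- numeric(length(folds))
  for (f in seq_along(folds)) {
    i <- folds[f]
    cfg <- config
    cfg$seed <- config$seed + i  # distinct, reproducible per fold
    s <- run_sampler(table, graph, priors, cfg, include_v = include_v,
                     holdout = i)
    nbi <- graph$neighbors[[i]]
    wstar <- if (length(nbi)) {
      wnb <- s$draws[, paste0("w[", nbi, "]"), drop = FALSE]
      rowMeans(wnb)
    } else 0
    eta <- s$draws[, "beta0"] +
      as.vector(s$draws[, grep("^beta\\[", colnames(s$draws)),
                        drop = FALSE] %*% table$X[i, ]) + wstar
    preds[f] <- mean(inv_logit(eta))
  }
  obs <- table$y[folds]
  ct <- cor.test(obs, preds)
  structure(list(
    predictions = data.frame(area_id = table$area_id[folds], observed = obs,
                             predicted = preds, stringsAsFactors = FALSE),
    r = unname(ct$estimate), p_value = ct$p.value,
    n_folds = length(folds)),
    class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("LOOCV over %d areas: r = %.3f (p = %.3g)\n",
              x$n_folds, x$r, x$p_value))
  invisible(x)
}
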