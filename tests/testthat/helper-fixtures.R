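# Shared fixtures: built in code at test time, no files on disk.

# short sampler budget for unit tests (not for convergence-gated checks)
quick_mcmc <- function(seed = 1, n_chains = 2, n_iterations = 2000,
                       n_burnin = 1000, thin = 2) {
  mcmc_config(n_chains = n_chains, n_iterations = n_iterations,
              n_burnin = n_burnin, thin = thin, seed = seed)
}

# 4-county path-graph toy with one covariate, drawn from the model itself
toy4 <- function(seed = 42, phi = 100, sw2 = 0.05) {
  set.seed(seed)
  x <- c(20, 25, 30, 35)
  g <- graph_from_edgelist(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  w <- sample_icar_field(g, sw2)
  mu <- inv_logit(logit(0.65) - 0.02 * 27.5 + 0.02 * x + w)
  y <- rbeta(4, mu * phi, (1 - mu) * phi)
  list(table = county_table(LETTERS[1:4], y,
                            matrix(x, 4, 1, dimnames = list(NULL, "sed"))),
       graph = g, x = x, y = y, phi = phi, sw2 = sw2)
}

# minimal bym_samples wrapper so postprocessing/diagnostics are testable on
# hand-constructed draw matrices
fake_samples <- function(draws, n_chains = 2, table = NULL) {
  structure(list(draws = draws,
                 chain = rep(seq_len(n_chains),
                             each = nrow(draws) / n_chains),
                 config = mcmc_config(n_chains = n_chains,
                                      n_iterations = 2 * nrow(draws),
                                      n_burnin = nrow(draws), thin = 1),
                 acceptance = list(list()),
                 table = table),
            class = "bym_samples")
}

# CSV writer for small in-test tables
write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
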