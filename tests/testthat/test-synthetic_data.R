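test_that("ICAR field draws live on the constraint, reproducibly", {
  # (distributional agreement with sigma_w2 * Q+ is checked in the
  # spectral-oracle acceptance test)
  g <- lattice_graph(3, 3, "rook")
  w <- sample_icar_field(g, 0.3, seed = 5)
  expect_lt(abs(sum(w)), 1e-10)
  expect_identical(sample_icar_field(g, 0.3, seed = 5), w)

  # marginal variances scale linearly with sigma_w2
  set.seed(6)
  W1 <- t(replicate(2000, sample_icar_field(g, 0.2)))
  set.seed(6)
  W2 <- t(replicate(2000, sample_icar_field(g, 0.8)))
  expect_equal(4 * apply(W1, 2, var), apply(W2, 2, var), tolerance = 1e-8)

  # per-component zero sums on a disconnected graph
  g2 <- graph_from_edgelist(6, rbind(c(1, 2), c(2, 3), c(4, 5), c(5, 6)))
  w2 <- sample_icar_field(g2, 1, seed = 1)
  comp <- connected_components(g2)
  expect_true(all(abs(tapply(w2, comp, sum)) < 1e-10))
})

test_that("generator collapses to its degenerate limit", {
  cfg <- generator_config(rows = 4, cols = 4, beta = c(sedentary = 0),
                          sigma_w2 = 1e-8, sigma_v2 = 1e-8, phi = 1e6,
                          beta0 = logit(0.68))
  ds <- generate_dataset(cfg)
  expect_true(all(abs(ds$table$y - 0.68) < 0.01))
})

test_that("default fixture centres prevalence near 68% across seeds", {
  means <- vapply(1:5, function(r) {
    cfg <- generator_config()
    cfg$seed <- cfg$seed + r
    mean(generate_dataset(cfg)$table$y)
  }, 0)
  expect_true(all(abs(means - 0.68) < 0.05))
})

test_that("generator output obeys its own declared structure", {
  ds <- generate_dataset(generator_config())
  expect_equal(ds$table$n_areas, 64L)
  expect_true(all(ds$table$y > 0 & ds$table$y < 1))
  comp <- connected_components(ds$graph)
  expect_true(all(abs(tapply(ds$truth$w, comp, sum)) < 1e-8))
  expect_identical(generate_dataset(generator_config())$table$y, ds$table$y)
  # saturating configuration is refused with advice
  expect_error(generate_dataset(generator_config(beta0 = 30)),
               "saturated")
})

test_that("conditional outcome variance follows mu(1-mu)/(1+phi)", {
  # hold mu essentially fixed and pool outcomes across replicates
  phi <- 50
  ys <- unlist(lapply(1:150, function(r) {
    cfg <- generator_config(rows = 2, cols = 2, beta = c(s = 0),
                            sigma_w2 = 1e-10, sigma_v2 = 1e-10, phi = phi,
                            beta0 = logit(0.7), seed = 1000 + r)
    generate_dataset(cfg)$table$y
  }))
  v_true <- 0.7 * 0.3 / (1 + phi)
  se_var <- sd((ys - mean(ys))^2) / sqrt(length(ys))
  expect_lt(abs(var(ys) - v_true), 3 * se_var)
  expect_lt(abs(mean(ys) - 0.7), 3 * sqrt(v_true / length(ys)))
})

test_that("file bundle reproduces the dataset from disk", {
  ds <- generate_dataset(generator_config(rows = 3, cols = 3))
  dir <- tempfile()
  paths <- write_dataset_bundle(ds, dir)
  expect_true(all(file.exists(paths)))
  tab <- read_county_table(paths["table"], outcome_col = "y",
                           name_col = "area_name",
                           outcome_unit = "proportion")
  expect_identical(tab$y, ds$table$y)
  g <- read_edgelist(paths["edges"], tab$area_id)
  expect_equal(g$edges, ds$graph$edges)
  polys <- read_polygons(paths["polygons"])
  expect_equal(polys$n_areas, 9L)
  g2 <- build_queen_adjacency(polys, rule = "rook")
  expect_equal(g2$edges, ds$graph$edges)
})

test_that("single-replicate recovery reports one row per parameter", {
  rep <- recovery_experiment(1, generator_config(rows = 4, cols = 4),
                             quick_mcmc(seed = 12))
  expect_equal(nrow(rep$results), 5L)
  expect_true(all(rep$results$covered %in% c(TRUE, FALSE)))
  expect_true(all(rep$aggregate$coverage %in% c(0, 1)))
})

test_that("coefficient RMSE shrinks from a 6x6 to a 10x10 lattice", {
  mk <- function(rows) {
    cfg <- generator_config(rows = rows, cols = rows,
                            beta = c(sedentary = 0.04),
                            covariates = list(sedentary = list(
                              type = "iid", mean = 25, scale = 5)),
                            sigma_w2 = 1e-4, sigma_v2 = 1e-4, phi = 500)
    rep <- recovery_experiment(4, cfg,
                               mcmc_config(n_chains = 2,
                                           n_iterations = 4000,
                                           n_burnin = 2000, thin = 2,
                                           seed = 17))
    rep$aggregate$rmse[rep$aggregate$param == "beta[sedentary]"]
  }
  expect_lt(mk(10), mk(6))
})

test_that("score identity: mean coefficient gradient at truth is near zero", {
  # finite-difference d/d beta of the joint log density, averaged over
  # replicates generated at the same truth, should centre at 0
  cfg <- generator_config(rows = 4, cols = 4)
  h <- 1e-5
  scores <- vapply(1:50, function(r) {
    c2 <- cfg
    c2$seed <- cfg$seed + 100 + r
    ds <- generate_dataset(c2)
    st <- ds$truth
    stp <- st; stp$beta <- st$beta + h
    stm <- st; stm$beta <- st$beta - h
    (log_posterior(stp, ds$table, ds$graph) -
       log_posterior(stm, ds$table, ds$graph)) / (2 * h)
  }, 0)
  # the prior contributes a deterministic -beta/sd^2 offset; remove it
  prior_grad <- -cfg$beta / 31.62^2
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - prior_grad), 3 * se)
})
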