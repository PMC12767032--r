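test_that("logit link is exact, stable and domain-checked", {
  expect_equal(inv_logit(0), 0.5)
  expect_equal(round(logit(0.682), 4), round(log(0.682 / 0.318), 4))
  p <- c(1e-8, 0.3, 0.682, 1 - 1e-8)
  expect_true(all(abs(inv_logit(logit(p)) - p) < 1e-12))
  expect_gt(inv_logit(-40), 0)   # no underflow to exactly 0
  expect_gt(inv_logit(-700), 0)
  expect_true(is.finite(inv_logit(700)) && is.finite(inv_logit(-700)))
  expect_error(logit(0), "domain error")
  expect_error(logit(1), "domain error")
})

test_that("beta density uses the mean-precision convention", {
  # Beta(1,1) is uniform
  expect_equal(beta_log_density(0.3, 0.5, 2), 0)
  # independent route: explicit log-gamma formula at mu=0.7, phi=50
  a <- 0.7 * 50; b <- 0.3 * 50
  ref <- (a - 1) * log(0.7) + (b - 1) * log(0.3) +
    lgamma(a + b) - lgamma(a) - lgamma(b)
  expect_equal(beta_log_density(0.7, 0.7, 50), ref)
  expect_error(beta_log_density(0, 0.5, 2), "domain error")
  # density integrates to 1
  for (pars in list(c(0.3, 5), c(0.68, 200))) {
    I <- integrate(function(y) exp(beta_log_density(y, pars[1], pars[2])),
                   0, 1, rel.tol = 1e-10)
    expect_equal(I$value, 1, tolerance = 1e-8)
  }
})

test_that("mean-precision draws have the implied mean and variance", {
  set.seed(123)
  n <- 1e5
  for (pars in list(c(0.3, 10), c(0.68, 200), c(0.9, 50))) {
    mu <- pars[1]; phi <- pars[2]
    y <- rbeta(n, mu * phi, (1 - mu) * phi)
    v <- mu * (1 - mu) / (1 + phi)
    se_mean <- sqrt(v / n)
    expect_lt(abs(mean(y) - mu), 3 * se_mean)
    # SE of the sample variance via fourth-moment estimate
    se_var <- sd((y - mean(y))^2) / sqrt(n)
    expect_lt(abs(var(y) - v), 3 * se_var)
  }
})

test_that("ICAR kernel matches hand-computed pairwise sums", {
  g <- graph_from_edgelist(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(icar_log_density(rep(0, 3), g, 1), 0)
  # w = (-1, 0, 1): both edges contribute 1, kernel -2/2 = -1; rank term 0
  expect_equal(icar_log_density(c(-1, 0, 1), g, 1), -1)
  # doubling sigma_w2 changes the value by ss/(4 s2) - ((n-c)/2) log 2
  w <- c(-0.3, 0.5, -0.2)
  s2 <- 0.4
  ss <- (w[1] - w[2])^2 + (w[2] - w[3])^2
  expect_equal(icar_log_density(w, g, 2 * s2) - icar_log_density(w, g, s2),
               ss / (4 * s2) - (2 / 2) * log(2))
  expect_error(icar_log_density(c(1, 1, 1), g, 1), "sum-to-zero")
})

test_that("log posterior reduces to i.i.d. beta when effects vanish", {
  toy <- toy4()
  n <- 4
  ybar <- mean(toy$y)
  st <- parameter_state(logit(ybar), 0, rep(0, n), rep(0, n), 1, 1, 50)
  st0 <- st; st0$phi <- 80
  # difference of two states with identical w, v, sigmas isolates the
  # likelihood + phi prior; compare against the i.i.d. beta reduction
  lp_diff <- log_posterior(st0, toy$table, toy$graph) -
    log_posterior(st, toy$table, toy$graph)
  ref <- sum(beta_log_density(toy$y, ybar, 80)) -
    sum(beta_log_density(toy$y, ybar, 50)) +
    dgamma(80, 1, rate = 0.01, log = TRUE) -
    dgamma(50, 1, rate = 0.01, log = TRUE)
  expect_equal(lp_diff, ref, tolerance = 1e-12)
})

test_that("log posterior differences match an independent expansion", {
  toy <- toy4()
  B <- sum_zero_basis(4)
  edges <- toy$graph$edges
  pr <- prior_spec(beta0_sd = 31.62)
  th1 <- c(0.2, 0.015, 0.3, -0.2, 0.1)
  th2 <- c(-0.4, 0.03, -0.1, 0.4, -0.25)
  mk_state <- function(th) parameter_state(
    th[1], th[2], as.vector(B %*% th[3:5]), rep(0, 4),
    toy$sw2, 1, toy$phi)
  # the v, sigma and phi prior terms cancel in the difference
  got <- log_posterior(mk_state(th1), toy$table, toy$graph, pr) -
    log_posterior(mk_state(th2), toy$table, toy$graph, pr)
  want <- oracle_reduced_kernel(th1, toy$y, toy$x, edges, B,
                                toy$phi, toy$sw2) -
    oracle_reduced_kernel(th2, toy$y, toy$x, edges, B, toy$phi, toy$sw2)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("likelihood concentrates as phi grows when y equals mu", {
  y <- c(0.6, 0.7, 0.75)
  g <- graph_from_edgelist(3, rbind(c(1, 2), c(2, 3)))
  tab <- county_table(c("a", "b", "c"), y)
  lik_term <- function(phi) {
    st <- parameter_state(0, numeric(0), rep(0, 3), logit(y), 1, 1, phi)
    sum(beta_log_density(y, linear_predictor(st, tab)$mu, phi))
  }
  phis <- c(10, 50, 200, 1000)
  expect_true(all(diff(vapply(phis, lik_term, 0)) > 0))
})

test_that("1-D slice of the posterior integrates identically on shifted grids", {
  toy <- toy4()
  pr <- prior_spec(beta0_sd = 31.62)
  f <- function(b0) vapply(b0, function(b) {
    st <- parameter_state(b, 0.02, rep(0, 4), rep(0, 4), 0.05, 0.01, 100)
    exp(log_posterior(st, toy$table, toy$graph, pr) + 20)
  }, 0)
  lo <- -3; hi <- 3; n <- 20001
  h <- (hi - lo) / n
  mid1 <- lo + (seq_len(n) - 0.5) * h
  I1 <- sum(f(mid1)) * h
  # translated grid: same rule started half a step later
  mid2 <- mid1 + h / 2
  I2 <- sum(f(mid2)) * h
  expect_equal(I1, I2, tolerance = 1e-6)
})
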