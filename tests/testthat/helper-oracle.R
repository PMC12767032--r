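# Independent oracles. Everything here is coded from the model definition
# directly (log-gamma beta density, pairwise ICAR kernel, dense grid
# integration) and never calls the package's own log_posterior or sampler
# internals, so it can serve as a second route in equivalence tests.

# fully expanded joint log kernel for the reduced 4-area toy:
# params th = (beta0, beta1, z1, z2, z3), w = B z on the sum-zero basis,
# v = 0, phi and sigma_w2 fixed, N(0, beta_sd) priors on beta0 and beta1
oracle_reduced_kernel <- function(th, y, x, edges, B, phi, sw2,
                                  beta_sd = 31.62) {
  w <- as.vector(B %*% th[3:5])
  eta <- th[1] + th[2] * x + w
  mu <- 1 / (1 + exp(-eta))
  a <- mu * phi
  b <- (1 - mu) * phi
  ll <- sum((a - 1) * log(y) + (b - 1) * log(1 - y) +
              lgamma(a + b) - lgamma(a) - lgamma(b))
  ss <- sum((w[edges[, 1]] - w[edges[, 2]])^2)
  ll - ss / (2 * sw2) - th[1]^2 / (2 * beta_sd^2) - th[2]^2 / (2 * beta_sd^2)
}

sum_zero_basis <- function(n) qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1]

# dense grid integration of the reduced toy posterior; returns marginal
# mean and central 95% interval for beta0 and beta1, plus grid spacings
oracle_grid_posterior <- function(y, x, edges, phi, sw2, beta_sd = 31.62,
                                  n_b = 41, n_z = 17, half_width = 6) {
  B <- sum_zero_basis(length(y))
  opt <- optim(rep(0, 5), function(th)
    -oracle_reduced_kernel(th, y, x, edges, B, phi, sw2, beta_sd),
    method = "BFGS", hessian = TRUE)
  sds <- sqrt(diag(solve(opt$hessian)))
  grid_b0 <- opt$par[1] + seq(-half_width, half_width, length.out = n_b) * sds[1]
  grid_b1 <- opt$par[2] + seq(-half_width, half_width, length.out = n_b) * sds[2]
  zg <- lapply(3:5, function(j)
    opt$par[j] + seq(-half_width, half_width, length.out = n_z) * sds[j])
  G <- expand.grid(b0 = grid_b0, b1 = grid_b1)
  M <- numeric(nrow(G))
  k0 <- -opt$value
  for (z1 in zg[[1]]) for (z2 in zg[[2]]) for (z3 in zg[[3]]) {
    w <- as.vector(B %*% c(z1, z2, z3))
    ss <- sum((w[edges[, 1]] - w[edges[, 2]])^2)
    K <- -ss / (2 * sw2) - G$b0^2 / (2 * beta_sd^2) -
      G$b1^2 / (2 * beta_sd^2) - k0
    for (i in seq_along(y)) {
      eta <- G$b0 + G$b1 * x[i] + w[i]
      mu <- 1 / (1 + exp(-eta))
      a <- mu * phi
      b <- (1 - mu) * phi
      K <- K + (a - 1) * log(y[i]) + (b - 1) * log(1 - y[i]) +
        lgamma(a + b) - lgamma(a) - lgamma(b)
    }
    M <- M + exp(K)
  }
  PM <- matrix(M, n_b, n_b)
  marg <- function(p, grid) {
    p <- p / sum(p)
    cdf <- cumsum(p)
    q <- function(pr) approx(cdf, grid, xout = pr, ties = "ordered")$y
    c(mean = sum(p * grid), lower = q(0.025), upper = q(0.975))
  }
  list(beta0 = marg(rowSums(PM), grid_b0),
       beta1 = marg(colSums(PM), grid_b1),
       h_b0 = diff(grid_b0[1:2]), h_b1 = diff(grid_b1[1:2]))
}

# Monte-Carlo standard errors for the posterior mean and a quantile of an
# MCMC draw vector, given an effective sample size
mcse_mean <- function(x, ess) sd(x) / sqrt(ess)
mcse_quantile <- function(x, ess, p) {
  sd(x) * sqrt(p * (1 - p) / ess) / dnorm(qnorm(p))
}
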