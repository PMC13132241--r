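# Independent estimators used to check the profile-REML fit.

# One-way ANOVA / method-of-moments variance components (closed form on
# balanced layouts, Searle's unbalanced n0 otherwise).
mom_oracle <- function(table) {
  g <- split(table$difference, table$participant_id)
  k <- length(g)
  n_i <- lengths(g)
  N <- sum(n_i)
  grand <- mean(unlist(g))
  means <- vapply(g, mean, 0)
  ssw <- sum(vapply(g, function(d) sum((d - mean(d))^2), 0))
  ssb <- sum(n_i * (means - grand)^2)
  mse <- ssw / (N - k)
  msb <- ssb / (k - 1)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  tau2 <- (msb - mse) / n0
  list(mu = grand, mu_balanced = mean(means), tau2 = tau2, sigma2 = mse)
}

# Dense-matrix restricted log-likelihood, evaluated from first principles
# (explicit covariance matrices, solve() and determinant()); used for a
# grid search over the variance ratio.
dense_reml_loglik <- function(table, lambda) {
  g <- split(table$difference, table$participant_id)
  Vinv_sum <- 0; Vinv_d_sum <- 0
  logdet <- 0; quads <- list()
  for (d in g) {
    n <- length(d)
    W <- diag(n) + lambda * matrix(1, n, n)
    Wi <- solve(W)
    logdet <- logdet + determinant(W, logarithm = TRUE)$modulus
    Vinv_sum <- Vinv_sum + sum(Wi)
    Vinv_d_sum <- Vinv_d_sum + sum(Wi %*% d)
    quads[[length(quads) + 1]] <- list(d = d, Wi = Wi)
  }
  mu <- Vinv_d_sum / Vinv_sum
  rss <- sum(vapply(quads, function(q) {
    r <- q$d - mu
    drop(t(r) %*% q$Wi %*% r)
  }, 0))
  N <- nrow(table)
  sigma2 <- rss / (N - 1)
  dev <- (N - 1) * log(sigma2) + as.numeric(logdet) + log(Vinv_sum)
  list(dev = dev, mu = mu, sigma2 = sigma2, tau2 = lambda * sigma2)
}

# Grid search over the variance ratio with two zoom passes.
grid_reml_oracle <- function(table, lambda_max = 50) {
  lo <- 0; hi <- lambda_max
  best <- NULL
  for (pass in 1:4) {
    grid <- seq(lo, hi, length.out = 81)
    devs <- vapply(grid, function(l) dense_reml_loglik(table, l)$dev, 0)
    i <- which.min(devs)
    best <- grid[i]
    step <- grid[2] - grid[1]
    lo <- max(0, best - step)
    hi <- best + step
  }
  dense_reml_loglik(table, best)
}
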