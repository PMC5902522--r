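# Independent Monte Carlo oracles: simulate raw Gaussian data and apply the
# textbook test definitions directly, without going through the package's
# vectorized machinery.

# Rejection rate of the equal-tail two-sided variance-ratio F test at a fixed
# true ratio delta.
oracle_f_reject_rate <- function(delta, n1, n2, alpha, nsim, seed) {
  set.seed(seed)
  lo <- qf(alpha / 2, n1 - 1, n2 - 1)
  hi <- qf(1 - alpha / 2, n1 - 1, n2 - 1)
  x1 <- matrix(rnorm(n1 * nsim, sd = sqrt(delta)), n1)
  x2 <- matrix(rnorm(n2 * nsim), n2)
  v1 <- colSums((x1 - rep(colMeans(x1), each = n1))^2) / (n1 - 1)
  v2 <- colSums((x2 - rep(colMeans(x2), each = n2))^2) / (n2 - 1)
  r <- v1 / v2
  rate <- mean(r < lo | r > hi)
  list(rate = rate, se = sqrt(rate * (1 - rate) / nsim))
}

# Hierarchical oracle for the catch-all Type II error of the F test under a
# lognormal prior on delta: draw delta, draw data, test, tally misses.
oracle_hierarchical_beta <- function(meanlog, sdlog, n1, n2, alpha, nsim, seed) {
  set.seed(seed)
  lo <- qf(alpha / 2, n1 - 1, n2 - 1)
  hi <- qf(1 - alpha / 2, n1 - 1, n2 - 1)
  delta <- rlnorm(nsim, meanlog, sdlog)
  x1 <- matrix(rnorm(n1 * nsim), n1) * rep(sqrt(delta), each = n1)
  x2 <- matrix(rnorm(n2 * nsim), n2)
  v1 <- colSums((x1 - rep(colMeans(x1), each = n1))^2) / (n1 - 1)
  v2 <- colSums((x2 - rep(colMeans(x2), each = n2))^2) / (n2 - 1)
  r <- v1 / v2
  beta <- mean(r >= lo & r <= hi)
  list(beta = beta, se = sqrt(beta * (1 - beta) / nsim))
}

# Write a seeded Gaussian two-group dataset to a temporary CSV and return its
# path (fixture builder for the file-reading layer).
write_two_group_csv <- function(n1, n2, delta, seed, dir = tempdir()) {
  set.seed(seed)
  df <- data.frame(
    value = c(rnorm(n1, sd = sqrt(delta)), rnorm(n2)),
    group = rep(c("a", "b"), c(n1, n2)))
  path <- tempfile("twogroup", tmpdir = dir, fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}
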