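# Shared fixtures: small standardized genotype matrices and panels built
# in code at test time.

std_cols <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  mu <- colMeans(x)
  s <- sqrt(colMeans(x^2) - mu^2)
  sweep(sweep(x, 2, mu), 2, s, "/")
}

# correlated standardized genotype-like matrix (Gaussian columns)
gauss_geno <- function(n, m, rho = 0, block = m) {
  stopifnot(m %% block == 0)
  out <- matrix(NA_real_, n, m)
  C <- chol(lderge:::block_correlation(block, rho, "exchangeable"))
  for (k in seq_len(m / block)) {
    ix <- seq.int((k - 1) * block + 1, k * block)
    out[, ix] <- matrix(rnorm(n * block), n, block) %*% C
  }
  std_cols(out)
}

# independent closed-form WLS oracle (normal equations via solve())
wls_oracle <- function(y, x, w) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  c(intercept = b[1], slope = b[2])
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
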