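# LD panel construction: correlation matrices, shrinkage, partitioning,
# eigen systems and serialization.

test_that("compute_ld_matrix reproduces hand-computed correlations and LD scores", {
  # orthogonal columns
  g <- std_cols(cbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1)))
  bl <- compute_ld_matrix(g)
  expect_equal(bl$R[1, 2], 0)
  expect_equal(bl$ld_scores, c(1, 1))
  # duplicated column: perfect LD
  g2 <- std_cols(cbind(c(-1, 0, 1), c(-1, 0, 1)))
  bl2 <- compute_ld_matrix(g2)
  expect_equal(bl2$R[1, 2], 1)
  expect_equal(bl2$ld_scores, c(2, 2))
  # anti-correlated pair
  g3 <- std_cols(cbind(c(-1, 0, 1), c(1, 0, -1)))
  expect_equal(compute_ld_matrix(g3)$R[1, 2], -1)
})

test_that("compute_ld_matrix rejects degenerate and unstandardized input", {
  g <- std_cols(matrix(rnorm(40), 10, 4))
  g[, 3] <- 0
  expect_error(compute_ld_matrix(g), "zero-variance.*3")
  expect_error(compute_ld_matrix(matrix(rnorm(20), 10, 2) + 5), "standardized")
  expect_error(compute_ld_matrix(matrix(nrow = 4, ncol = 0)), "zero columns")
})

test_that("shrinkage interpolates between the sample matrix and the identity", {
  set.seed(1)
  g <- std_cols(matrix(rnorm(50 * 5), 50, 5))
  bl <- compute_ld_matrix(g)
  expect_equal(shrink_ld(bl, 0)$R, bl$R)
  expect_equal(shrink_ld(bl, 1)$R, diag(5))
  expect_error(shrink_ld(bl, 1.2), "\\[0, 1\\]")
  # monotone off-diagonal decay in the intensity
  off <- upper.tri(bl$R)
  mags <- sapply(c(0.1, 0.4, 0.8), function(a) max(abs(shrink_ld(bl, a)$R[off])))
  expect_true(all(diff(mags) < 0))
})

test_that("auto shrinkage matches an independently coded Ledoit-Wolf oracle", {
  set.seed(42)
  g <- std_cols(matrix(rnorm(50 * 5), 50, 5))
  bl <- compute_ld_matrix(g)
  shr <- shrink_ld(bl, "auto", genotypes = g)
  # oracle: explicit loops over pairs, var-hat of r_ij from products w_k = x_ki x_kj
  n <- nrow(g)
  num <- den <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    w <- g[, i] * g[, j]
    r <- mean(w)
    num <- num + n / (n - 1)^3 * sum((w - r)^2)
    den <- den + r^2
  }
  alpha_oracle <- min(1, max(0, num / den))
  expect_equal(attr(shr, "intensity"), alpha_oracle, tolerance = 1e-10)
  off <- upper.tri(bl$R)
  expect_true(all(abs(shr$R[off]) < abs(bl$R[off])))
})

test_that("block partitioning merges linked pairs and respects chromosomes", {
  v10 <- variant_table(paste0("v", 1:10), "1", (1:10) * 1e4, "A", "G", 0.3)
  none <- tibble::tibble(i = integer(), j = integer(), r = double())
  b <- partition_blocks(v10, none, r_threshold = 0.00373)
  expect_equal(nrow(b), 10) # all singletons
  # two tight clusters 200 kb apart -> 2 blocks
  v <- variant_table(paste0("v", 1:10), "1",
                     c((1:5) * 1e3, 2e5 + (1:5) * 1e3), "A", "G", 0.3)
  pairs <- expand.grid(i = 1:5, j = 1:5)
  within <- rbind(
    transform(pairs, r = 0.9),
    transform(pairs, i = i + 5, j = j + 5, r = 0.9)
  )
  b2 <- partition_blocks(v, within[within$i < within$j, ], 0.00373)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$start, c(1L, 6L))
  # chain of linked neighbors -> single block by transitivity
  chain <- tibble::tibble(i = 1:5, j = 2:6, r = 0.5)
  v6 <- variant_table(paste0("v", 1:6), "1", (1:6) * 1e4, "A", "G", 0.3)
  expect_equal(nrow(partition_blocks(v6, chain, 0.00373)), 1)
  # chromosome change always breaks, even across a linked pair
  v6b <- variant_table(paste0("v", 1:6), c("1", "1", "1", "2", "2", "2"),
                       c(1:3 * 1e4, 1:3 * 1e4), "A", "G", 0.3)
  b3 <- partition_blocks(v6b, tibble::tibble(i = 3, j = 4, r = 0.9), 0.00373)
  expect_true(any(b3$end == 3))
  expect_error(
    partition_blocks(v6b[c(2, 1, 3:6), ], none, 0.00373),
    "sorted"
  )
})

test_that("no linked pair within the window crosses a block boundary (brute force)", {
  set.seed(7)
  m <- 60
  v <- variant_table(paste0("v", 1:m), "1", cumsum(sample(1e3:4e4, m)), "A", "G", 0.3)
  pr <- expand.grid(i = 1:m, j = 1:m)
  pr <- pr[pr$i < pr$j, ]
  pr$r <- ifelse(runif(nrow(pr)) < 0.05, runif(nrow(pr), 0.1, 1), 0)
  thr <- 0.05; win <- 1e5
  b <- partition_blocks(v, pr, thr, win)
  block_of <- rep(seq_len(nrow(b)), b$end - b$start + 1)
  linked <- pr[abs(pr$r) > thr & abs(v$pos[pr$i] - v$pos[pr$j]) <= win, ]
  expect_true(all(block_of[linked$i] == block_of[linked$j]))
  # contiguous full cover
  expect_equal(length(block_of), m)
})

test_that("eigen systems match hand-computed decompositions and conserve trace", {
  id3 <- lderge:::ld_block_from_R(diag(3))
  es <- eigendecompose_block(id3)
  expect_equal(es$d, c(1, 1, 1))
  expect_equal(es$n_retained, 3L)

  perfect <- lderge:::ld_block_from_R(matrix(c(1, 1, 1, 1), 2, 2))
  es2 <- eigendecompose_block(perfect)
  expect_equal(es2$d, 2)          # zero eigenvalue filtered
  expect_equal(es2$n_retained, 1L)
  expect_equal(es2$trace, 2)      # pre-filter trace = block dimension

  half <- lderge:::ld_block_from_R(matrix(c(1, 0.5, 0.5, 1), 2, 2))
  es3 <- eigendecompose_block(half)
  expect_equal(es3$d, c(1.5, 0.5))

  # random PSD correlation: eigen equation, orthonormality, Frobenius identity
  set.seed(3)
  g <- std_cols(matrix(rnorm(200 * 8), 200, 8))
  bl <- compute_ld_matrix(g)
  es4 <- eigendecompose_block(bl)
  expect_lt(max(abs(bl$R %*% es4$u - es4$u %*% diag(es4$d))), 1e-8)
  expect_lt(max(abs(crossprod(es4$u) - diag(es4$n_retained))), 1e-8)
  expect_equal(es4$trace, 8, tolerance = 1e-6)
  expect_equal(sum(es4$d^2), sum(bl$R^2), tolerance = 1e-6) # = sum of ld_scores
  expect_equal(sum(bl$ld_scores), sum(bl$R^2), tolerance = 1e-10)
})

test_that("panel serialization round-trips exactly and rejects corruption", {
  set.seed(9)
  g <- gauss_geno(100, 20, rho = 0.5, block = 10)
  panel <- build_panel(g, blocks = 10)
  path <- tempfile(fileext = ".json")
  save_panel(panel, path)
  back <- load_panel(path)
  expect_identical(length(back$blocks), 2L)
  for (k in 1:2) {
    expect_identical(back$blocks[[k]]$d, panel$blocks[[k]]$d)
    expect_identical(back$blocks[[k]]$u, unname(panel$blocks[[k]]$u))
    expect_equal(back$blocks[[k]]$variants, panel$blocks[[k]]$variants)
  }
  expect_identical(back$eigenvalue_floor, panel$eigenvalue_floor)
  expect_identical(nrow(back$variants), 20L) # conservation

  txt <- readLines(path)
  writeLines(sub('"n_blocks":2', '"n_blocks":3', txt), path)
  expect_error(load_panel(path), "corrupt")
  empty <- tempfile(fileext = ".json")
  writeLines("{}", empty)
  expect_error(load_panel(empty), "not an lderge panel")
})
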