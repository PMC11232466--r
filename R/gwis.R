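# Genome-wide interaction scan (GWIS): per-variant marginal regressions of
# the phenotype on a variant and its variant-by-exposure product term.

standardize_cols <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  mu <- colMeans(x)
  s <- sqrt(colMeans(x^2) - mu^2) # denominator n, matching correlation LD
  sweep(sweep(x, 2, mu), 2, s, "/")
}

check_standardized <- function(x, what, tol = 1e-6) {
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  if (any(abs(mu) > tol) || any(abs(v - 1) > tol)) {
    abort(sprintf("%s must be standardized: mean 0, variance 1 (denominator n)", what))
  }
  invisible(TRUE)
}

#' Residualize a phenotype against fixed-effect covariates
#'
#' Ordinary least-squares residuals of `y` on a covariate matrix (which
#' must include an intercept column), as used to pre-adjust phenotypes for
#' age, sex, genetic principal components and the exposure of interest
#' before the interaction scan.
#'
#' @param y Numeric phenotype vector.
#' @param covariates Numeric matrix or data frame of covariates including
#'   an intercept column.
#'
#' @return Residual vector orthogonal to every covariate column.
#' @export
residualize_phenotype <- function(y, covariates) {
  X <- as.matrix(covariates)
  if (nrow(X) != length(y)) abort("covariate rows must match length(y)")
  if (!any(apply(X, 2, function(cc) max(abs(cc - cc[1])) < 1e-12))) {
    abort("covariates must include an intercept (constant) column")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X) %||% as.character(seq_len(ncol(X)))
    dropped <- bad[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    abort(sprintf(
      "rank-deficient covariate matrix; collinear column(s): %s",
      paste(dropped, collapse = ", ")
    ))
  }
  as.vector(qr.resid(qrX, y))
}

gwis_tibble <- function(variants, n, beta, se, z) {
  tibble::tibble(
    chrom = variants$chrom, id = variants$id, pos = variants$pos,
    a1 = variants$a1, a2 = variants$a2, n = as.integer(n),
    beta_int = beta, se_int = se, z_int = z
  )
}

#' Linear genome-wide interaction scan
#'
#' For each variant `j`, fits the two-predictor linear regression of the
#' residualized phenotype on the variant `G_j` and the product term
#' `S_j = G_j * E` (with intercept) and returns the Wald Z-score of the
#' interaction coefficient. Fully vectorized across variants through
#' closed-form normal equations.
#'
#' @param genotypes Standardized genotype matrix `N x M`.
#' @param exposure Standardized exposure vector of length `N`.
#' @param y_res Residualized phenotype vector.
#' @param variants Optional variant metadata tibble; defaults to synthetic
#'   placeholders.
#'
#' @return Summary-statistics tibble with columns `chrom`, `id`, `pos`,
#'   `a1`, `a2`, `n`, `beta_int`, `se_int`, `z_int`, in variant order.
#'   Variants whose interaction term has zero variance are dropped with a
#'   warning.
#' @export
run_gwis_linear <- function(genotypes, exposure, y_res, variants = NULL) {
  G <- as.matrix(genotypes)
  n <- nrow(G)
  m <- ncol(G)
  stopifnot(length(exposure) == n, length(y_res) == n)
  check_standardized(G, "genotype columns")
  check_standardized(matrix(exposure, ncol = 1), "exposure")
  if (is.null(variants)) variants <- default_variants(m)
  yc <- y_res - mean(y_res)
  E <- as.vector(exposure)
  G2 <- G^2
  mG <- colMeans(G)
  mS <- as.vector(crossprod(G, E)) / n
  GG <- colSums(G2)
  GS <- as.vector(crossprod(G2, E))
  SS <- as.vector(crossprod(G2, E^2))
  GY <- as.vector(crossprod(G, yc))
  SY <- as.vector(crossprod(G, E * yc))
  a11 <- GG - n * mG^2
  a12 <- GS - n * mG * mS
  a22 <- SS - n * mS^2
  b1 <- GY
  b2 <- SY
  det <- a11 * a22 - a12^2
  ok <- a22 > 1e-10 & det > 1e-10
  if (!all(ok)) {
    warn(sprintf("dropping %d variant(s) with degenerate interaction term", sum(!ok)))
  }
  beta2 <- (a11 * b2 - a12 * b1) / det
  beta1 <- (a22 * b1 - a12 * b2) / det
  rss <- sum(yc^2) - beta1 * b1 - beta2 * b2
  sigma2 <- pmax(rss, 0) / (n - 3)
  se2 <- sqrt(sigma2 * a11 / det)
  out <- gwis_tibble(variants, n, beta2, se2, beta2 / se2)
  out[ok, , drop = FALSE]
}

#' Logistic genome-wide interaction scan
#'
#' Per-variant logistic regression of a binary outcome on covariates, the
#' variant and the variant-by-exposure product term; the interaction
#' Z-score is the Wald statistic of the product-term coefficient.
#'
#' @param genotypes Standardized genotype matrix.
#' @param exposure Standardized exposure vector.
#' @param y_binary 0/1 outcome vector with both classes present.
#' @param covariates Optional covariate matrix (an intercept is always
#'   added internally).
#' @param variants Optional variant metadata tibble.
#'
#' @return Summary-statistics tibble as in [run_gwis_linear()]. Variants
#'   with non-converged or separated fits are dropped with a warning.
#' @export
run_gwis_logistic <- function(genotypes, exposure, y_binary, covariates = NULL,
                              variants = NULL) {
  G <- as.matrix(genotypes)
  n <- nrow(G)
  m <- ncol(G)
  y <- as.integer(y_binary)
  if (!all(y %in% c(0L, 1L))) abort("y_binary must be 0/1")
  if (length(unique(y)) < 2L) abort("both outcome classes must be present")
  if (is.null(variants)) variants <- default_variants(m)
  E <- as.vector(exposure)
  base <- cbind(`(Intercept)` = rep(1, n), covariates)
  p <- ncol(base) + 2L
  beta <- se <- rep(NA_real_, m)
  fam <- binomial()
  for (j in seq_len(m)) {
    X <- cbind(base, g = G[, j], s = G[, j] * E)
    fit <- suppressWarnings(glm.fit(X, y, family = fam))
    if (!fit$converged || fit$boundary) next
    Rm <- qr.R(fit$qr)
    piv <- fit$qr$pivot
    covmat <- tryCatch(chol2inv(Rm), error = function(e) NULL)
    if (is.null(covmat)) next
    sj <- sqrt(diag(covmat))[order(piv)][p]
    if (!is.finite(sj) || sj > 100) next # separation / degenerate
    beta[j] <- fit$coefficients[p]
    se[j] <- sj
  }
  ok <- is.finite(beta) & is.finite(se)
  if (!all(ok)) {
    warn(sprintf("dropping %d variant(s): separated or non-converged logistic fits", sum(!ok)))
  }
  out <- gwis_tibble(variants, n, beta, se, beta / se)
  out$model <- "logistic"
  out[ok, , drop = FALSE]
}

AMBIGUOUS_PAIRS <- c("A/T", "T/A", "C/G", "G/C")

#' Align summary statistics to a panel's variant order and alleles
#'
#' Intersects study summary statistics with a panel's variant table by ID,
#' flips interaction Z-scores (and effect sizes) when the study's counted
#' allele is the panel's other allele, drops strand-ambiguous variants
#' (A/T, C/G) and allele-mismatched variants, and returns rows in panel
#' order.
#'
#' @param stats Summary-statistics tibble (needs `id`, `a1`, `a2`, `z_int`).
#' @param panel_variants Panel variant tibble (see [variant_table()]).
#'
#' @return The aligned summary-statistics tibble; fails if fewer than half
#'   the panel variants can be matched (a guard against mismatched genome
#'   builds).
#' @export
align_alleles <- function(stats, panel_variants) {
  if (anyDuplicated(stats$id)) abort("duplicate variant IDs in summary statistics")
  if (anyDuplicated(panel_variants$id)) abort("duplicate variant IDs in panel")
  idx <- match(panel_variants$id, stats$id)
  matched <- !is.na(idx)
  if (mean(matched) < 0.5) {
    abort(sprintf(
      "only %.1f%% of panel variants present in summary statistics; check genome build",
      100 * mean(matched)
    ))
  }
  out <- stats[idx[matched], , drop = FALSE]
  pv <- panel_variants[matched, , drop = FALSE]
  same <- out$a1 == pv$a1 & out$a2 == pv$a2
  flipped <- out$a1 == pv$a2 & out$a2 == pv$a1
  ambiguous <- paste(out$a1, out$a2, sep = "/") %in% AMBIGUOUS_PAIRS
  keep <- (same | flipped) & !ambiguous
  sign <- ifelse(flipped, -1, 1)
  out$z_int <- out$z_int * sign
  if ("beta_int" %in% names(out)) out$beta_int <- out$beta_int * sign
  out$a1 <- pv$a1
  out$a2 <- pv$a2
  out[keep, , drop = FALSE]
}
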