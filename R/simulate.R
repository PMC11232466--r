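# Synthetic-data engine: block-correlated genotypes, exposures, phenotypes
# under the polygenic GE model, liability-threshold binary traits, a direct
# moment-model summary-statistic sampler, and the calibration harness.

#' Simulation configuration
#'
#' Bundles and validates the generative parameters of the polygenic GE
#' model `Y = G beta + S gamma + eps1 E + eps0`, with
#' `beta_j ~ N(0, h2_g / M)` on all variants, `gamma_j` supported on a
#' random causal subset and scaled so the total GE variance equals
#' `h2_I`, `eps1 ~ N(0, sigma2_1)` (residual-by-exposure interaction) and
#' `eps0` absorbing the remainder so `Var(Y) = 1`.
#'
#' @param n Subjects.
#' @param m Variants (divisible by `block_size`).
#' @param block_size Variants per LD block.
#' @param within_block_rho Within-block correlation parameter in `[0, 1)`.
#' @param structure Correlation profile: `"ar1"` (default; heterogeneous
#'   LD scores) or `"exchangeable"`.
#' @param maf_range Range minor allele frequencies are drawn from.
#' @param h2_g Narrow-sense heritability (additive genetic variance).
#' @param h2_I GE interaction variance proportion — the target parameter.
#' @param sigma2_1 Residual-by-exposure ("RxE") interaction proportion.
#' @param causal_fraction_ge Fraction of variants with nonzero interaction
#'   effects.
#' @param exposure_law `"standard_normal"` or `"bernoulli"`.
#' @param exposure_p Success probability for a Bernoulli exposure.
#' @param prevalence Optional population prevalence for a binary trait.
#' @param replicates Replicates for [run_experiment()].
#' @param seed Integer seed for [run_experiment()].
#'
#' @return A validated `simulation_config` list, with `sigma2_0` filled in.
#' @export
simulation_config <- function(n = 2000L, m = 2000L, block_size = 50L,
                              within_block_rho = 0.9,
                              structure = c("ar1", "exchangeable"),
                              maf_range = c(0.05, 0.5),
                              h2_g = 0.2, h2_I = 0.02, sigma2_1 = 0,
                              causal_fraction_ge = 0.05,
                              exposure_law = c("standard_normal", "bernoulli"),
                              exposure_p = 0.5,
                              prevalence = NULL,
                              replicates = 500L, seed = 1L) {
  structure_ <- match.arg(structure)
  exposure_law <- match.arg(exposure_law)
  if (m %% block_size != 0L) abort("m must be divisible by block_size")
  if (within_block_rho < 0 || within_block_rho >= 1) {
    abort("within_block_rho must lie in [0, 1)")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) abort("maf range must lie in (0, 0.5]")
  if (h2_g + h2_I + sigma2_1 >= 1) abort("h2_g + h2_I + sigma2_1 must be < 1")
  if (h2_g < 0 || h2_I < 0 || sigma2_1 < 0) abort("variance components must be non-negative")
  if (!is.null(prevalence) && (prevalence <= 0 || prevalence >= 1)) {
    abort("prevalence must lie in (0, 1)")
  }
  structure(
    list(
      n = as.integer(n), m = as.integer(m), block_size = as.integer(block_size),
      within_block_rho = within_block_rho, structure = structure_,
      maf_range = maf_range, h2_g = h2_g, h2_I = h2_I, sigma2_1 = sigma2_1,
      sigma2_0 = 1 - h2_g - h2_I - sigma2_1,
      causal_fraction_ge = causal_fraction_ge,
      exposure_law = exposure_law, exposure_p = exposure_p,
      prevalence = prevalence,
      replicates = as.integer(replicates), seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

block_correlation <- function(block_size, rho, structure = "ar1") {
  if (structure == "exchangeable") {
    R <- matrix(rho, block_size, block_size)
    diag(R) <- 1
    R
  } else {
    rho^abs(outer(seq_len(block_size), seq_len(block_size), "-"))
  }
}

#' Exact-correlation synthetic LD panel
#'
#' Builds an eigen-system panel whose block LD matrices are exact AR(1) or
#' exchangeable correlation matrices — the idealized "blocky LD" used in
#' calibration studies. AR(1) is the default because it yields
#' heterogeneous per-variant LD scores, which the diagonal baseline needs
#' for an identifiable slope (under equal-size exchangeable blocks every
#' variant has the same LD score).
#'
#' @param n_blocks Number of blocks.
#' @param block_size Variants per block.
#' @param rho Within-block correlation parameter.
#' @param structure `"ar1"` or `"exchangeable"`.
#' @param eigenvalue_floor Retention floor for eigenvalues.
#'
#' @return An `lderge_panel`.
#' @export
synthetic_panel <- function(n_blocks, block_size, rho,
                            structure = c("ar1", "exchangeable"),
                            eigenvalue_floor = 1e-6) {
  structure_ <- match.arg(structure)
  m <- n_blocks * block_size
  variants <- default_variants(m)
  R <- block_correlation(block_size, rho, structure_)
  systems <- lapply(seq_len(n_blocks), function(k) {
    ix <- seq.int((k - 1L) * block_size + 1L, k * block_size)
    bl <- ld_block_from_R(R, variants[ix, , drop = FALSE])
    eigendecompose_block(bl, eigenvalue_floor, block_id = k)
  })
  new_panel(systems, n_ref = NA_integer_, eigenvalue_floor = eigenvalue_floor,
            provenance = sprintf("synthetic %s rho=%g", structure_, rho))
}

#' Simulate block-correlated standardized genotypes
#'
#' Draws a latent multivariate normal per block with the configured
#' within-block correlation, thresholds each variant at its
#' Hardy-Weinberg cutpoints (genotype probabilities `(1-p)^2`, `2p(1-p)`,
#' `p^2` at allele frequency `p`) to dosages 0/1/2, then standardizes
#' columns. Thresholding attenuates the realized correlation below the
#' latent parameter; downstream estimation uses the realized (in-sample)
#' LD, so this costs no calibration.
#'
#' @param config A [simulation_config()].
#' @return List with the standardized `genotypes` matrix, the `blocks`
#'   table and the `variants` metadata (column `maf` holds each variant's
#'   drawn allele frequency).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  bs <- config$block_size
  n_blocks <- config$m %/% bs
  Rl <- block_correlation(bs, config$within_block_rho, config$structure)
  Cf <- chol(Rl)
  maf <- runif(config$m, config$maf_range[1], config$maf_range[2])
  G <- matrix(NA_real_, n, config$m)
  for (k in seq_len(n_blocks)) {
    ix <- seq.int((k - 1L) * bs + 1L, k * bs)
    latent <- matrix(rnorm(n * bs), n, bs) %*% Cf
    p <- maf[ix]
    lo <- qnorm((1 - p)^2)
    hi <- qnorm((1 - p)^2 + 2 * p * (1 - p))
    g <- (sweep(latent, 2, lo, ">") + sweep(latent, 2, hi, ">")) * 1
    G[, ix] <- g
  }
  v <- apply(G, 2, var)
  if (any(v < 1e-12)) {
    abort("monomorphic simulated variant(s); increase n or the MAF lower bound")
  }
  variants <- default_variants(config$m)
  variants$maf <- pmin(maf, 1 - maf)
  starts <- seq(1L, config$m, by = bs)
  list(
    genotypes = standardize_cols(G),
    blocks = tibble::tibble(
      block_id = seq_len(n_blocks), start = starts, end = starts + bs - 1L,
      chrom = variants$chrom[starts]
    ),
    variants = variants
  )
}

#' Simulate a standardized exposure
#'
#' @param n Subjects.
#' @param law `"standard_normal"` or `"bernoulli"`.
#' @param p Bernoulli success probability.
#' @return Exposure vector standardized to sample mean 0, variance 1.
#' @export
simulate_exposure <- function(n, law = "standard_normal", p = 0.5) {
  e <- switch(law,
    standard_normal = rnorm(n),
    bernoulli = rbinom(n, 1L, p),
    abort(sprintf("unknown exposure law '%s'", law))
  )
  if (var(e) < 1e-12) abort("degenerate exposure draw; increase n")
  as.vector(scale(e)) * sqrt(n / (n - 1))
}

#' Simulate a phenotype under the polygenic GE model
#'
#' Generates `Y = G beta + (G * E) gamma + eps1 E + eps0` with
#' `beta ~ N(0, h2_g / M)` on all variants and `gamma` drawn on a random
#' causal subset with variance `h2_I / M_causal`, so the total GE variance
#' equals `h2_I` regardless of the causal fraction.
#'
#' @param G Standardized genotype matrix.
#' @param E Standardized exposure vector.
#' @param config A [simulation_config()].
#' @return List with the continuous phenotype `y` and a `truth` tibble
#'   recording generative parameters and realized component variances.
#' @export
simulate_phenotype <- function(G, E, config) {
  n <- nrow(G)
  m <- ncol(G)
  if (length(E) != n) abort("exposure length must match genotype rows")
  if (m != config$m) abort("genotype columns must match config$m")
  beta <- rnorm(m, 0, sqrt(config$h2_g / m))
  m_causal <- max(1L, round(config$causal_fraction_ge * m))
  causal <- sample.int(m, m_causal)
  gamma <- numeric(m)
  if (config$h2_I > 0) {
    gamma[causal] <- rnorm(m_causal, 0, sqrt(config$h2_I / m_causal))
  }
  g_part <- as.vector(G %*% beta)
  ge_part <- as.vector((G * E) %*% gamma)
  rxe_part <- rnorm(n, 0, sqrt(config$sigma2_1)) * E
  noise <- rnorm(n, 0, sqrt(config$sigma2_0))
  y <- g_part + ge_part + rxe_part + noise
  truth <- tibble::tibble(
    h2_g = config$h2_g, h2_I = config$h2_I, sigma2_1 = config$sigma2_1,
    sigma2_0 = config$sigma2_0, m_causal = m_causal,
    var_g = var(g_part), var_ge = var(ge_part),
    var_rxe = var(rxe_part), var_noise = var(noise), var_y = var(y)
  )
  list(y = y, truth = truth, causal = causal)
}

#' Threshold a liability into a binary trait
#'
#' Standardizes the liability and applies the population-prevalence
#' cutoff `qnorm(1 - prevalence)`.
#'
#' @param liability Continuous liability vector.
#' @param prevalence Population prevalence in (0, 1).
#' @return Integer 0/1 vector.
#' @export
simulate_binary <- function(liability, prevalence) {
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must lie in (0, 1)")
  l <- as.vector(scale(liability))
  as.integer(l > qnorm(1 - prevalence))
}

# Per-block factor of Sigma = n h2 L/m + intercept R in the eigen-basis:
# Sigma = U diag(lambda) U' with lambda = n h2 d^2 / m + intercept d.
direct_block_factors <- function(panel, n, m, h2_I, intercept) {
  lapply(panel$blocks, function(b) {
    lambda <- n * h2_I * b$d^2 / m + intercept * b$d
    if (any(lambda < -1e-8 * max(1, max(abs(lambda))))) {
      abort("moment covariance is indefinite; check h2_I and intercept")
    }
    b$u %*% (sqrt(pmax(lambda, 0)) * diag(length(lambda)))
  })
}

direct_z_draws <- function(panel, n, m, h2_I, intercept, draws) {
  factors <- direct_block_factors(panel, n, m, h2_I, intercept)
  do.call(rbind, lapply(seq_along(panel$blocks), function(k) {
    q <- length(panel$blocks[[k]]$d)
    factors[[k]] %*% matrix(rnorm(q * draws), q, draws)
  }))
}

#' Draw GWIS summary statistics directly from the moment model
#'
#' Samples the interaction Z-score vector block-wise from a multivariate
#' normal with covariance `Sigma = N h2_I L / M + intercept * R`
#' (`L = R'R`), built in each block's eigen-basis and floored at
#' eigenvalue zero. This is the fast path for calibration studies: no
#' individual-level data are generated.
#'
#' @param panel An `lderge_panel`.
#' @param n Nominal GWIS sample size.
#' @param h2_I True GE interaction variance proportion.
#' @param intercept Composite intercept `c + (K(E)-1)(h2_I + sigma2_1)`;
#'   `1 + 2 (h2_I + sigma2_1)` for a standard-normal exposure without
#'   confounding. Must be non-negative.
#' @param m Variant count behind the statistics; defaults to the panel's.
#'
#' @return Summary-statistics tibble aligned to the panel.
#' @export
simulate_sumstats_direct <- function(panel, n, h2_I, intercept, m = NULL) {
  if (intercept < 0) abort("intercept must be non-negative")
  m <- m %||% nrow(panel$variants)
  z <- as.vector(direct_z_draws(panel, n, m, h2_I, intercept, 1L))
  v <- panel$variants
  gwis_tibble(v, n, beta = z / sqrt(n), se = rep(1 / sqrt(n), length(z)), z = z)
}

scenario_intercept <- function(h2_I, sigma2_1, kurtosis_E = 3) {
  1 + (kurtosis_E - 1) * (h2_I + sigma2_1)
}

metrics_row <- function(scenario, h2_I, sigma2_1, method, est, p, truth, alpha) {
  s <- sd(est)
  tibble::tibble(
    scenario = scenario, h2_I = h2_I, sigma2_1 = sigma2_1, method = method,
    mean_estimate = mean(est),
    precision = if (s > 0) 1 / s else 1e12,
    rmse = sqrt(mean((est - truth)^2)),
    positive_rate = if (all(is.na(p))) NA_real_ else mean(p < alpha, na.rm = TRUE),
    replicates = length(est)
  )
}

#' Run a calibration experiment grid
#'
#' For each true `h2_I` (and RxE proportion) scenario, draws replicated
#' summary statistics from the direct moment-model sampler on an exact
#' synthetic panel built from `config`, fits the requested estimators,
#' and reports per-scenario metrics: mean estimate, precision (inverse
#' empirical SD), RMSE against truth, and the one-sided positive rate at
#' level `alpha` (type-I error under the null, power otherwise).
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()]; `replicates`, `n`, `m`,
#'   `block_size`, `within_block_rho`, `structure` and `seed` are used.
#' @param methods Estimators to run: subset of `"lder_ge"`, `"ldsc_ge"`.
#' @param h2_I_grid True values of the interaction variance; defaults to
#'   `config$h2_I`.
#' @param sigma2_1_grid RxE proportions; defaults to `config$sigma2_1`.
#' @param jackknife Compute jackknife p-values (needed for positive
#'   rates)?
#' @param alpha Test level for the positive rate.
#'
#' @return Tibble of class `lderge_metrics`, one row per scenario and
#'   method.
#' @export
run_experiment <- function(config, methods = c("lder_ge", "ldsc_ge"),
                           h2_I_grid = NULL, sigma2_1_grid = NULL,
                           jackknife = TRUE, alpha = 0.05) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$replicates < 2L) abort("need at least 2 replicates")
  methods <- match.arg(methods, several.ok = TRUE)
  h2_I_grid <- h2_I_grid %||% config$h2_I
  sigma2_1_grid <- sigma2_1_grid %||% config$sigma2_1
  set.seed(config$seed)
  panel <- synthetic_panel(config$m %/% config$block_size, config$block_size,
                           config$within_block_rho, config$structure)
  ld <- panel_ld_scores(panel)
  var_block <- rep(
    vapply(panel$blocks, function(b) b$block_id, integer(1)),
    vapply(panel$blocks, function(b) nrow(b$variants), integer(1))
  )
  kurt <- if (config$exposure_law == "bernoulli") {
    bernoulli_kurtosis(config$exposure_p)
  } else 3
  out <- list()
  for (s1 in sigma2_1_grid) {
    for (h2 in h2_I_grid) {
      intercept <- scenario_intercept(h2, s1, kurt)
      Z <- direct_z_draws(panel, config$n, config$m, h2, intercept,
                          config$replicates)
      tr <- transform_z_matrix(panel, Z)
      scen <- sprintf("h2_I=%g,sigma2_1=%g", h2, s1)
      for (meth in methods) {
        est <- p <- rep(NA_real_, config$replicates)
        for (r in seq_len(config$replicates)) {
          fit <- if (meth == "lder_ge") {
            lderge_fit(
              tibble::tibble(block_id = tr$block_id, d = tr$d,
                             z_tilde = tr$z_tilde[, r]),
              n = config$n, m = config$m, jackknife = jackknife
            )
          } else {
            ldsc_ge_fit(
              tibble::tibble(z_int = Z[, r]), ld,
              n = config$n, m = config$m, jackknife = jackknife,
              block_id = var_block
            )
          }
          est[r] <- fit$h2_I
          if (jackknife) p[r] <- fit$p_value
        }
        out[[length(out) + 1L]] <-
          metrics_row(scen, h2, s1, meth, est, p, h2, alpha)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("lderge_metrics", class(res))
  res
}

#' Plot calibration metrics
#'
#' Per-scenario precision of each estimator, side by side.
#'
#' @param object An `lderge_metrics` tibble from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lderge_metrics
#' @export
autoplot.lderge_metrics <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = factor(.data$h2_I), y = .data$precision, fill = .data$method)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "true GE interaction variance", y = "precision (1 / empirical SD)",
      fill = NULL
    )
}
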