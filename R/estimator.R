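# LDER-GE core: eigen-transform of GWIS Z-scores, iterative weighted least
# squares on the moment equation, delete-block jackknife, Wald inference,
# and the LDSC-style diagonal baseline.

# Batched transform: Zt[k, ] = D^{-1/2} U' Z for every column of Z.
transform_z_matrix <- function(panel, Z) {
  stopifnot(is.matrix(Z))
  offsets <- cumsum(c(0L, vapply(panel$blocks, function(b) nrow(b$variants), integer(1))))
  pieces <- lapply(seq_along(panel$blocks), function(k) {
    b <- panel$blocks[[k]]
    rows <- seq.int(offsets[k] + 1L, offsets[k + 1L])
    (t(b$u) / sqrt(b$d)) %*% Z[rows, , drop = FALSE]
  })
  list(
    z_tilde = do.call(rbind, pieces),
    d = unlist(lapply(panel$blocks, function(b) b$d), use.names = FALSE),
    block_id = rep(
      vapply(panel$blocks, function(b) b$block_id, integer(1)),
      vapply(panel$blocks, function(b) b$n_retained, integer(1))
    )
  )
}

#' Transform GWIS Z-scores by block eigen systems
#'
#' Whitens the interaction Z-score vector block by block:
#' `z_tilde = D^{-1/2} U' z`, using only the retained principal components
#' of each block's LD matrix. Under the moment model the squared
#' transformed scores have expectation `N h2_I d / M + intercept`, linear
#' in the eigenvalue `d` — the regression surface the estimator fits.
#'
#' @param stats Summary-statistics tibble aligned to the panel (see
#'   [align_alleles()]); needs columns `id` and `z_int`.
#' @param panel An `lderge_panel`.
#'
#' @return Tibble with one row per retained component: `block_id`, `d`
#'   (eigenvalue) and `z_tilde`.
#' @export
transform_zscores <- function(stats, panel) {
  idx <- match(panel$variants$id, stats$id)
  if (anyNA(idx)) {
    abort(sprintf(
      "summary statistics do not cover the panel: %d panel variant(s) missing",
      sum(is.na(idx))
    ))
  }
  z <- matrix(stats$z_int[idx], ncol = 1)
  tr <- transform_z_matrix(panel, z)
  tibble::tibble(block_id = tr$block_id, d = tr$d, z_tilde = as.vector(tr$z_tilde))
}

# Closed-form weighted least squares of y on (1, x).
wls_slope_intercept <- function(y, x, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  c(slope = slope, intercept = (swy - slope * swx) / sw)
}

# Iterative WLS of squared (transformed) statistics on x = n * d / m.
# weight_fun(h, intercept) must return positive weights for the current
# iterate; iteration starts at h = 0, intercept = 1 and stops when the
# slope moves by less than tol.
iwls_fit <- function(y, x, weight_fun, max_iter = 30L, tol = 1e-6) {
  if (length(unique(x)) < 2L) {
    abort("slope unidentifiable: all regressors (eigenvalues or LD scores) identical")
  }
  h <- 0
  intc <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- weight_fun(h, intc)
    est <- wls_slope_intercept(y, x, w)
    if (abs(est[["slope"]] - h) < tol) {
      h <- est[["slope"]]; intc <- est[["intercept"]]
      converged <- TRUE
      break
    }
    h <- est[["slope"]]; intc <- est[["intercept"]]
  }
  list(h2 = h, intercept = intc, iterations = iter, converged = converged)
}

#' Delete-block jackknife standard error
#'
#' Groups blocks into `n_groups` contiguous groups, deletes one group at a
#' time, re-estimates with the supplied fit callable and returns the
#' jackknife standard error
#' `sqrt((B - 1) / B * sum((theta_b - mean(theta))^2))` together with the
#' leave-one-out estimates. A deletion that leaves the design
#' unidentifiable is merged with its neighboring group, with a warning.
#'
#' @param fit_fun Function taking a logical keep-mask over elements and
#'   returning a scalar estimate.
#' @param block_ids Integer block label per element (contiguous runs).
#' @param n_groups Target number of jackknife groups (capped at the number
#'   of distinct blocks).
#' @param identifiable Optional predicate on the keep-mask; deletions for
#'   which it returns `FALSE` trigger group merging.
#'
#' @return List with `se`, `leave_one_out` and `n_groups`.
#' @export
jackknife_se <- function(fit_fun, block_ids, n_groups = 200L,
                         identifiable = NULL) {
  ub <- unique(block_ids)
  if (length(ub) < 2L) abort("jackknife needs at least 2 blocks")
  n_groups <- min(as.integer(n_groups), length(ub))
  group_of_block <- ceiling(seq_along(ub) / (length(ub) / n_groups))
  repeat {
    groups <- group_of_block[match(block_ids, ub)]
    ug <- unique(groups)
    bad <- NULL
    if (!is.null(identifiable)) {
      for (g in ug) {
        if (!identifiable(groups != g)) { bad <- g; break }
      }
    }
    if (is.null(bad)) break
    warn(sprintf("jackknife group %d leaves an unidentifiable design; merging with neighbor", bad))
    neighbor <- if (bad < max(group_of_block)) bad + 1L else bad - 1L
    group_of_block[group_of_block == bad] <- neighbor
    group_of_block <- match(group_of_block, sort(unique(group_of_block)))
    if (length(unique(group_of_block)) < 2L) {
      abort("jackknife degenerated to a single group")
    }
  }
  theta <- vapply(ug, function(g) fit_fun(groups != g), double(1))
  B <- length(theta)
  se <- sqrt((B - 1) / B * sum((theta - mean(theta))^2))
  list(se = se, leave_one_out = theta, n_groups = B)
}

#' One-sided Wald test for a variance proportion
#'
#' @param h2_I Point estimate of the GE interaction variance proportion.
#' @param se Standard error (jackknife).
#' @return One-sided p-value `1 - Phi(h2_I / se)`. With `se = 0` the
#'   degenerate limits 0 (positive estimate) or 1 are returned with a
#'   warning.
#' @export
wald_test <- function(h2_I, se) {
  if (se < 0) abort("se must be non-negative")
  if (se == 0) {
    warn("degenerate test: se = 0")
    return(if (h2_I > 0) 0 else 1)
  }
  pnorm(h2_I / se, lower.tail = FALSE)
}

new_ge_fit <- function(method, est, se, p, loo, n_groups, n, m, n_components,
                       data) {
  structure(
    list(
      method = method, h2_I = est$h2, intercept = est$intercept,
      se = se, p_value = p, leave_one_out = loo,
      n_blocks_jackknife = n_groups, iterations = est$iterations,
      converged = est$converged, n = n, m = m, n_components = n_components,
      data = data
    ),
    class = "lderge_fit"
  )
}

ge_fit_engine <- function(y, x, scale_var, block_id, weight_builder, method,
                          n, m, max_iter, tol, jackknife, n_groups) {
  stopifnot(length(y) == length(x), length(x) == length(block_id))
  fit_mask <- function(mask) {
    iwls_fit(y[mask], x[mask],
             function(h, intc) weight_builder(h, intc, scale_var[mask]),
             max_iter = max_iter, tol = tol)
  }
  full <- fit_mask(rep(TRUE, length(y)))
  if (!full$converged) {
    warn(sprintf("%s fit did not converge in %d iterations; returning last iterate",
                 method, full$iterations))
  }
  se <- NA_real_; p <- NA_real_; loo <- double(0); B <- 0L
  if (jackknife) {
    jk <- jackknife_se(
      function(mask) fit_mask(mask)$h2,
      block_id, n_groups,
      identifiable = function(mask) length(unique(x[mask])) >= 2L
    )
    se <- jk$se
    loo <- jk$leave_one_out
    B <- jk$n_groups
    p <- wald_test(full$h2, se)
  }
  new_ge_fit(method, full, se, p, loo, B, n, m, length(y),
             tibble::tibble(block_id = block_id, x = x, scale = scale_var, y = y))
}

#' Fit the full-LD (LDER-GE) GE interaction variance estimator
#'
#' Regresses squared eigen-transformed interaction Z-scores on
#' `x = N d / M` with a free intercept by iterative weighted least
#' squares. Weights follow
#' `w = min(d, 1) / (N h2 d / M + intercept)^2`, with the current
#' composite intercept standing in for `1 + 2(h_I^2 + sigma_1^2)` (the two
#' are not separately identified) and the slope clipped at zero inside the
#' weights only. The point estimate is unconstrained and may be negative.
#' Standard errors come from a delete-block jackknife and the p-value from
#' a one-sided Wald test.
#'
#' @param transformed Tibble from [transform_zscores()] (columns
#'   `block_id`, `d`, `z_tilde`).
#' @param n GWIS sample size `N`.
#' @param m Number of variants `M` behind the summary statistics.
#' @param max_iter,tol Iteration controls for the weighted least squares.
#' @param jackknife Compute delete-block jackknife SE and p-value?
#' @param n_groups Number of contiguous jackknife groups (capped at the
#'   number of blocks).
#'
#' @return An object of class `lderge_fit` with elements `h2_I`,
#'   `intercept`, `se`, `p_value`, `leave_one_out`, `n_blocks_jackknife`,
#'   `iterations`, `converged`, `method`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
lderge_fit <- function(transformed, n, m, max_iter = 30L, tol = 1e-6,
                       jackknife = TRUE, n_groups = 200L) {
  if (n <= 0 || m <= 0) abort("n and m must be positive")
  d <- transformed$d
  ge_fit_engine(
    y = transformed$z_tilde^2,
    x = n * d / m,
    scale_var = d,
    block_id = transformed$block_id,
    weight_builder = function(h, intc, d) {
      pmin(d, 1) / (n * max(h, 0) * d / m + max(intc, 0.05))^2
    },
    method = "lder_ge", n = n, m = m,
    max_iter = max_iter, tol = tol, jackknife = jackknife, n_groups = n_groups
  )
}

#' Fit the LDSC-style diagonal baseline estimator
#'
#' Regresses raw squared interaction Z-scores on `x = N l / M`, where `l`
#' is the per-variant LD score, with a free intercept and iterative
#' weights `1 / (2 (N h2 l / M + intercept)^2 l)`. This baseline uses only
#' the diagonal of the squared LD matrix; it is the comparison point for
#' the full-LD estimator.
#'
#' @param stats Summary-statistics tibble aligned to the panel (column
#'   `z_int`).
#' @param ld_scores Per-variant LD scores aligned to `stats` (all
#'   `>= 1 - 1e-8`).
#' @param n,m,max_iter,tol,jackknife,n_groups As in [lderge_fit()].
#' @param block_id Optional block label per variant for the jackknife;
#'   defaults to contiguous equal chunks.
#'
#' @return An `lderge_fit` object with `method = "ldsc_ge"`.
#' @export
ldsc_ge_fit <- function(stats, ld_scores, n, m, max_iter = 30L, tol = 1e-6,
                        jackknife = TRUE, n_groups = 200L, block_id = NULL) {
  if (n <= 0 || m <= 0) abort("n and m must be positive")
  z <- stats$z_int
  stopifnot(length(ld_scores) == length(z))
  if (any(ld_scores < 1 - 1e-8)) abort("LD scores must be >= 1")
  if (is.null(block_id)) {
    block_id <- ceiling(seq_along(z) / max(1, length(z) / 200))
  }
  ge_fit_engine(
    y = z^2,
    x = n * ld_scores / m,
    scale_var = ld_scores,
    block_id = as.integer(block_id),
    weight_builder = function(h, intc, l) {
      1 / (2 * (n * max(h, 0) * l / m + max(intc, 0.05))^2 * l)
    },
    method = "ldsc_ge", n = n, m = m,
    max_iter = max_iter, tol = tol, jackknife = jackknife, n_groups = n_groups
  )
}

#' Annotate the composite regression intercept
#'
#' The fitted intercept estimates the composite
#' `c + (K(E) - 1)(h_I^2 + sigma_1^2)`, where `c` captures confounding
#' inflation and `K(E)` is the exposure kurtosis (2 extra units for a
#' standard normal exposure, 0 for a balanced binary one). The
#' residual-by-exposure variance `sigma_1^2` is not separately
#' identifiable from the intercept and is deliberately not solved for.
#'
#' @param intercept Fitted composite intercept.
#' @param kurtosis_E Kurtosis of the exposure variable (3 for a standard
#'   normal).
#'
#' @return Tibble with the composite value, the kurtosis, the interaction
#'   factor `K(E) - 1`, and a note on non-identifiability.
#' @export
intercept_components <- function(intercept, kurtosis_E) {
  if (!is.finite(kurtosis_E)) abort("kurtosis must be finite")
  tibble::tibble(
    intercept = intercept,
    kurtosis_E = kurtosis_E,
    interaction_factor = kurtosis_E - 1,
    decomposition = sprintf(
      "intercept = c + %.6g * (h2_I + sigma2_1); sigma2_1 not identifiable",
      kurtosis_E - 1
    )
  )
}

#' Kurtosis of a standardized Bernoulli exposure
#'
#' @param p Success probability in (0, 1).
#' @return `(1 - 6 p q) / (p q) + 3` with `q = 1 - p`; equals 1 at
#'   `p = 0.5`.
#' @export
bernoulli_kurtosis <- function(p) {
  if (any(p <= 0 | p >= 1)) abort("p must lie in (0, 1)")
  q <- 1 - p
  (1 - 6 * p * q) / (p * q) + 3
}

#' Effective sample-size gain implied by a precision gain
#'
#' Under the root-N scaling of standard errors, a relative precision gain
#' `g` (e.g. 0.23 for 23%) is equivalent to increasing the sample size by
#' `((1 + g)^2 - 1) * 100` percent.
#'
#' @param precision_gain Relative precision improvement (fraction).
#' @return Equivalent percentage increase in sample size.
#' @export
effective_sample_size_gain <- function(precision_gain) {
  ((1 + precision_gain)^2 - 1) * 100
}

#' @export
print.lderge_fit <- function(x, ...) {
  cat(sprintf(
    "<lderge_fit: %s>\n  h2_I      = % .6f\n  intercept = % .6f\n  se        = %s\n  p (one-sided) = %s\n  components = %d, jackknife groups = %d, iterations = %d%s\n",
    x$method, x$h2_I, x$intercept,
    if (is.na(x$se)) "NA" else sprintf("%.6f", x$se),
    if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 4),
    x$n_components, x$n_blocks_jackknife, x$iterations,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Tidy a GE variance fit
#'
#' @param x An `lderge_fit`.
#' @param ... Unused.
#' @return One row per model term (`h2_I`, `intercept`) with `estimate`,
#'   `std.error`, `statistic`, `p.value` (inference on the variance term
#'   only).
#' @method tidy lderge_fit
#' @export
tidy.lderge_fit <- function(x, ...) {
  tibble::tibble(
    term = c("h2_I", "intercept"),
    estimate = c(x$h2_I, x$intercept),
    std.error = c(x$se, NA_real_),
    statistic = c(if (is.na(x$se) || x$se == 0) NA_real_ else x$h2_I / x$se, NA_real_),
    p.value = c(x$p_value, NA_real_)
  )
}

#' Glance at a GE variance fit
#'
#' @param x An `lderge_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit-level summaries.
#' @method glance lderge_fit
#' @export
glance.lderge_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, h2_I = x$h2_I, intercept = x$intercept, se = x$se,
    p_value = x$p_value, n = x$n, m = x$m, n_components = x$n_components,
    n_blocks_jackknife = x$n_blocks_jackknife, iterations = x$iterations,
    converged = x$converged
  )
}

#' Diagnostic plot of the moment regression
#'
#' Bins retained components (or variants, for the diagonal baseline) by
#' their regressor `x = N d / M`, plots bin-mean squared statistics
#' against bin-mean `x`, and overlays the fitted line
#' `intercept + h2_I x`.
#'
#' @param object An `lderge_fit`.
#' @param bins Number of quantile bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lderge_fit
#' @export
autoplot.lderge_fit <- function(object, bins = 20, ...) {
  df <- object$data |>
    dplyr::mutate(bin = dplyr::ntile(.data$x, bins)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$h2_I, linetype = 2
    ) +
    ggplot2::labs(
      x = "N d / M", y = "mean squared (transformed) Z",
      title = sprintf("%s moment regression: h2_I = %.4f", object$method, object$h2_I)
    )
}
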