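# Block-wise LD reference panel: computation, shrinkage, partitioning,
# eigen-decomposition and (de)serialization.

#' Construct a variant metadata table
#'
#' Builds the tibble of per-variant metadata used throughout the package:
#' variant identifier, chromosome, 1-based position, counted allele `a1`,
#' other allele `a2` and minor allele frequency.
#'
#' @param id Character vector of unique variant IDs.
#' @param chrom Chromosome labels (coerced to character).
#' @param pos Integer base-pair positions (1-based).
#' @param a1,a2 Allele strings; `a1` is the counted/effect allele.
#' @param maf Minor allele frequencies in `[0, 0.5]`.
#'
#' @return A tibble with columns `id`, `chrom`, `pos`, `a1`, `a2`, `maf`.
#' @export
variant_table <- function(id, chrom, pos, a1, a2, maf) {
  tb <- tibble::tibble(
    id = as.character(id), chrom = as.character(chrom),
    pos = as.integer(pos), a1 = as.character(a1), a2 = as.character(a2),
    maf = as.double(maf)
  )
  if (anyDuplicated(tb$id)) abort("variant IDs must be unique")
  if (any(tb$pos <= 0L)) abort("positions must be positive (1-based)")
  if (any(tb$a1 == tb$a2)) abort("a1 and a2 must differ")
  if (any(tb$maf < 0 | tb$maf > 0.5)) abort("maf must lie in [0, 0.5]")
  tb
}

default_variants <- function(m, chrom = "1", spacing_bp = 10000L) {
  variant_table(
    id = sprintf("rs%06d", seq_len(m)), chrom = chrom,
    pos = seq_len(m) * spacing_bp,
    a1 = "A", a2 = "G", maf = rep(0.3, m)
  )
}

new_ld_block <- function(R, ld_scores, variants, n_ref) {
  structure(
    list(R = R, ld_scores = ld_scores, variants = variants, n_ref = n_ref),
    class = "ld_block"
  )
}

#' Compute a block LD matrix from standardized genotypes
#'
#' Forms the variant correlation matrix `R = G'G / n_ref` from a matrix of
#' standardized genotypes (columns: variants; rows: reference subjects),
#' forces the diagonal to exactly 1, and computes per-variant LD scores as
#' row sums of the element-wise squared matrix (the diagonal of `R'R`).
#'
#' @param genotypes Numeric matrix `n_ref x m`; each column must have sample
#'   mean 0 and variance 1 (denominator `n`), to within 1e-6.
#' @param variants Optional variant metadata tibble (see [variant_table()]);
#'   defaults to synthetic placeholder metadata.
#'
#' @return An `ld_block`: list with elements `R`, `ld_scores`, `variants`,
#'   `n_ref`.
#' @export
compute_ld_matrix <- function(genotypes, variants = NULL) {
  genotypes <- as.matrix(genotypes)
  n_ref <- nrow(genotypes)
  m <- ncol(genotypes)
  if (m == 0L) abort("no variants: genotype matrix has zero columns")
  if (n_ref < 2L) abort("need at least 2 reference subjects")
  mu <- colMeans(genotypes)
  v <- colMeans(genotypes^2) - mu^2
  if (any(v < 1e-12)) {
    abort(sprintf(
      "zero-variance genotype column(s): %s",
      paste(which(v < 1e-12), collapse = ", ")
    ))
  }
  if (any(abs(mu) > 1e-6) || any(abs(v - 1) > 1e-6)) {
    abort("genotype columns must be standardized (mean 0, variance 1, denominator n)")
  }
  R <- crossprod(genotypes) / n_ref
  R <- (R + t(R)) / 2
  diag(R) <- 1
  if (is.null(variants)) variants <- default_variants(m)
  stopifnot(nrow(variants) == m)
  new_ld_block(R, rowSums(R^2), variants, n_ref)
}

ld_block_from_R <- function(R, variants = NULL, n_ref = NA_integer_) {
  R <- (R + t(R)) / 2
  diag(R) <- 1
  if (is.null(variants)) variants <- default_variants(ncol(R))
  new_ld_block(R, rowSums(R^2), variants, n_ref)
}

#' Ledoit-Wolf shrinkage intensity for a correlation matrix
#'
#' Estimates the optimal linear shrinkage intensity toward the identity for
#' a sample correlation matrix, following the Ledoit-Wolf/Schafer-Strimmer
#' estimator: the ratio of the summed estimation variances of the
#' off-diagonal correlations to their summed squares, clipped to `[0, 1]`.
#'
#' @param genotypes Standardized genotype matrix used to build the block.
#' @return Shrinkage intensity in `[0, 1]`.
#' @export
shrinkage_intensity <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (n < 3L) abort("need at least 3 subjects to estimate shrinkage intensity")
  x <- scale(genotypes) * sqrt(n / (n - 1)) # unit variance, denominator n
  x[is.nan(x)] <- 0
  R <- crossprod(x) / n
  # var-hat(r_ij) = n/(n-1)^3 * sum_k (w_kij - mean_k w_kij)^2, w_kij = x_ki x_kj
  W2 <- crossprod(x^2) # sum_k w_kij^2
  varr <- n / (n - 1)^3 * (W2 - n * R^2)
  off <- upper.tri(R)
  denom <- sum(R[off]^2)
  if (denom <= 0) return(1)
  min(1, max(0, sum(varr[off]) / denom))
}

#' Linearly shrink a block LD matrix toward the identity
#'
#' Applies `R_shrunk = (1 - alpha) R + alpha I` and recomputes LD scores.
#' With `intensity = "auto"` the Ledoit-Wolf optimal intensity is estimated
#' from the reference genotypes (which must then be supplied).
#'
#' @param block An `ld_block`.
#' @param intensity Shrinkage intensity in `[0, 1]`, or `"auto"`.
#' @param genotypes Standardized genotype matrix, required for `"auto"`.
#'
#' @return The shrunk `ld_block`; the applied intensity is stored as
#'   attribute `"intensity"`.
#' @export
shrink_ld <- function(block, intensity = "auto", genotypes = NULL) {
  stopifnot(inherits(block, "ld_block"))
  if (identical(intensity, "auto")) {
    if (is.null(genotypes)) {
      abort("intensity = \"auto\" requires the reference genotypes")
    }
    alpha <- shrinkage_intensity(genotypes)
  } else {
    alpha <- as.double(intensity)
    if (is.na(alpha) || alpha < 0 || alpha > 1) {
      abort("shrinkage intensity must lie in [0, 1]")
    }
  }
  m <- ncol(block$R)
  R <- (1 - alpha) * block$R + alpha * diag(m)
  out <- new_ld_block(R, rowSums(R^2), block$variants, block$n_ref)
  attr(out, "intensity") <- alpha
  out
}

#' Partition position-sorted variants into quasi-independent LD blocks
#'
#' Splits the genome into contiguous blocks such that no variant pair with
#' `|r| > r_threshold` and separated by at most `window_bp` base pairs spans
#' a block boundary, and chromosome changes always break blocks. Linked
#' pairs are merged by single linkage, yielding the minimal blocks
#' satisfying the constraint.
#'
#' @param variants Variant metadata tibble, position-sorted within each
#'   chromosome.
#' @param r_band Tibble (or data frame) of pairwise LD with columns `i`,
#'   `j` (variant indices into `variants`) and `r`; only entries with
#'   `|r| > r_threshold` matter.
#' @param r_threshold Positive LD threshold; the reference-panel default in
#'   large biobank builds is `1.96 / sqrt(n_ref)`.
#' @param window_bp Window in base pairs within which linked pairs must not
#'   be split (default 100 kb).
#'
#' @return Tibble with one row per block: `block_id`, `start`, `end`
#'   (variant indices, inclusive) and `chrom`.
#' @export
partition_blocks <- function(variants, r_band, r_threshold, window_bp = 100000L) {
  if (r_threshold <= 0) abort("r_threshold must be positive")
  m <- nrow(variants)
  ord_ok <- unlist(lapply(split(seq_len(m), factor(variants$chrom, levels = unique(variants$chrom))),
                          function(ix) !is.unsorted(variants$pos[ix])))
  if (!all(ord_ok)) abort("variants must be position-sorted within chromosome")
  # boundary after index k is forbidden if some linked pair (i <= k < j)
  # is within the window and on the same chromosome
  forbid <- rep(FALSE, m - 1L)
  if (nrow(r_band) > 0) {
    i <- pmin(r_band$i, r_band$j)
    j <- pmax(r_band$i, r_band$j)
    keep <- abs(r_band$r) > r_threshold & i != j &
      variants$chrom[i] == variants$chrom[j] &
      abs(variants$pos[i] - variants$pos[j]) <= window_bp
    for (k in which(keep)) {
      forbid[seq.int(i[k], j[k] - 1L)] <- TRUE
    }
  }
  # chromosome changes always break
  chrom_change <- variants$chrom[-1L] != variants$chrom[-m]
  forbid[chrom_change] <- FALSE
  cut_after <- which(!forbid)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, m)
  tibble::tibble(
    block_id = seq_along(starts), start = starts, end = ends,
    chrom = variants$chrom[starts]
  )
}

#' Eigen-decompose a block LD matrix
#'
#' Computes `R = U D U'` and retains the principal components whose
#' eigenvalues exceed the floor (default `1e-6`), dropping numerically
#' trivial directions.
#'
#' @param block An `ld_block`.
#' @param eigenvalue_floor Retain components with eigenvalue strictly above
#'   this value.
#' @param block_id Integer label carried into the result.
#'
#' @return An `eigen_system`: list with orthonormal eigenvector matrix `u`
#'   (columns), descending eigenvalues `d`, `n_retained`, `block_id`,
#'   `variants`, `ld_scores` and the pre-filter trace `trace`.
#' @export
eigendecompose_block <- function(block, eigenvalue_floor = 1e-6, block_id = 1L) {
  stopifnot(inherits(block, "ld_block"))
  if (any(!is.finite(block$R))) abort("LD matrix contains non-finite entries")
  m <- ncol(block$R)
  if (all(block$R[upper.tri(block$R)] == 0)) {
    # diagonal LD: decomposition is trivial; keep a deterministic variant
    # order (ties would otherwise be permuted by the LAPACK solver)
    ord <- order(diag(block$R), decreasing = TRUE)
    es <- list(values = diag(block$R)[ord], vectors = diag(m)[, ord, drop = FALSE])
  } else {
    es <- eigen(block$R, symmetric = TRUE)
  }
  if (min(es$values) < -1e-8 * max(1, max(es$values))) {
    abort("LD matrix is not positive semi-definite; shrink before decomposing")
  }
  keep <- es$values > eigenvalue_floor
  structure(
    list(
      u = es$vectors[, keep, drop = FALSE],
      d = es$values[keep],
      n_retained = sum(keep),
      block_id = as.integer(block_id),
      variants = block$variants,
      ld_scores = block$ld_scores,
      trace = sum(es$values)
    ),
    class = "eigen_system"
  )
}

new_panel <- function(blocks, n_ref, eigenvalue_floor, provenance = "lderge") {
  variants <- dplyr::bind_rows(lapply(blocks, function(b) b$variants))
  structure(
    list(
      blocks = blocks, variants = variants, n_ref = n_ref,
      eigenvalue_floor = eigenvalue_floor, provenance = provenance
    ),
    class = "lderge_panel"
  )
}

#' Build an eigen-system LD panel from standardized genotypes
#'
#' Convenience pipeline over [compute_ld_matrix()], optional [shrink_ld()]
#' and [eigendecompose_block()] for a set of contiguous blocks.
#'
#' @param genotypes Standardized genotype matrix (subjects x variants).
#' @param blocks Block table as returned by [partition_blocks()], or an
#'   integer block size to cut equal contiguous blocks.
#' @param variants Optional variant metadata for all columns.
#' @param shrink Shrinkage intensity in `[0,1]`, `"auto"`, or `0` for none.
#' @param eigenvalue_floor Eigenvalue retention floor.
#'
#' @return An `lderge_panel`: list of per-block `eigen_system`s plus the
#'   combined variant table, `n_ref` and the floor used.
#' @export
build_panel <- function(genotypes, blocks, variants = NULL, shrink = 0,
                        eigenvalue_floor = 1e-6) {
  genotypes <- as.matrix(genotypes)
  m <- ncol(genotypes)
  if (is.null(variants)) variants <- default_variants(m)
  if (is.numeric(blocks) && length(blocks) == 1L) {
    starts <- seq(1L, m, by = as.integer(blocks))
    blocks <- tibble::tibble(
      block_id = seq_along(starts), start = starts,
      end = pmin(starts + as.integer(blocks) - 1L, m),
      chrom = variants$chrom[starts]
    )
  }
  systems <- lapply(seq_len(nrow(blocks)), function(k) {
    ix <- seq.int(blocks$start[k], blocks$end[k])
    g <- genotypes[, ix, drop = FALSE]
    bl <- compute_ld_matrix(g, variants[ix, , drop = FALSE])
    if (!identical(shrink, 0) && !identical(shrink, 0L)) {
      bl <- shrink_ld(bl, shrink, genotypes = g)
    }
    eigendecompose_block(bl, eigenvalue_floor, block_id = blocks$block_id[k])
  })
  new_panel(systems, n_ref = nrow(genotypes), eigenvalue_floor = eigenvalue_floor)
}

#' @export
print.lderge_panel <- function(x, ...) {
  cat(sprintf(
    "<lderge_panel> %d blocks, %d variants, %d retained components (n_ref = %s, floor = %g)\n",
    length(x$blocks), nrow(x$variants),
    sum(vapply(x$blocks, function(b) b$n_retained, integer(1))),
    format(x$n_ref), x$eigenvalue_floor
  ))
  invisible(x)
}

#' Summarize a panel as a tibble
#'
#' @param x An `lderge_panel`.
#' @param ... Unused.
#' @return One row per block: `block_id`, `m`, `n_retained`, `trace`.
#' @method as_tibble lderge_panel
#' @export
as_tibble.lderge_panel <- function(x, ...) {
  tibble::tibble(
    block_id = vapply(x$blocks, function(b) b$block_id, integer(1)),
    m = vapply(x$blocks, function(b) nrow(b$variants), integer(1)),
    n_retained = vapply(x$blocks, function(b) b$n_retained, integer(1)),
    trace = vapply(x$blocks, function(b) b$trace, double(1))
  )
}

PANEL_FORMAT_VERSION <- 1L

#' Save / load an LD panel
#'
#' Serializes an `lderge_panel` to a self-describing JSON container holding
#' per-block eigenvalues, eigenvectors and variant metadata at full double
#' precision, together with `n_ref`, the eigenvalue floor and provenance.
#' `load_panel()` validates the format version and block count and rebuilds
#' the panel bit-exactly.
#'
#' @param panel An `lderge_panel`.
#' @param path File path.
#' @return `save_panel()` returns `path` invisibly; `load_panel()` returns
#'   the reconstructed `lderge_panel`.
#' @export
save_panel <- function(panel, path) {
  stopifnot(inherits(panel, "lderge_panel"))
  payload <- list(
    format = "lderge_panel",
    format_version = PANEL_FORMAT_VERSION,
    n_ref = panel$n_ref,
    eigenvalue_floor = panel$eigenvalue_floor,
    provenance = panel$provenance,
    n_blocks = length(panel$blocks),
    blocks = lapply(panel$blocks, function(b) {
      list(
        block_id = b$block_id, n_retained = b$n_retained, trace = b$trace,
        d = b$d, u = b$u, ld_scores = b$ld_scores,
        variants = as.data.frame(b$variants)
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_panel
#' @export
load_panel <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort(sprintf("cannot parse panel file '%s': %s", path, conditionMessage(e)))
  )
  if (!identical(payload$format, "lderge_panel")) {
    abort("not an lderge panel file (missing format marker)")
  }
  if (!identical(as.integer(payload$format_version), PANEL_FORMAT_VERSION)) {
    abort(sprintf("unsupported panel format version %s", payload$format_version))
  }
  blocks_raw <- payload$blocks
  # simplifyVector gives a data frame of blocks when shapes are homogeneous,
  # otherwise a list; normalize to a list of rows
  if (is.data.frame(blocks_raw)) {
    blocks_raw <- lapply(seq_len(nrow(blocks_raw)), function(k) {
      lapply(blocks_raw, function(col) if (is.list(col)) col[[k]] else col[k])
    })
  }
  if (length(blocks_raw) != payload$n_blocks) {
    abort(sprintf(
      "corrupt panel: header declares %d blocks but %d present",
      payload$n_blocks, length(blocks_raw)
    ))
  }
  blocks <- lapply(blocks_raw, function(b) {
    u <- b$u
    if (!is.matrix(u)) u <- do.call(rbind, u)
    d <- as.double(b$d)
    if (length(d) != ncol(u)) abort("corrupt panel: eigenvalue/eigenvector mismatch")
    structure(
      list(
        u = u, d = d, n_retained = as.integer(b$n_retained),
        block_id = as.integer(b$block_id),
        variants = tibble::as_tibble(b$variants),
        ld_scores = as.double(b$ld_scores), trace = as.double(b$trace)
      ),
      class = "eigen_system"
    )
  })
  panel <- new_panel(blocks, as.integer(payload$n_ref),
                     as.double(payload$eigenvalue_floor),
                     provenance = payload$provenance)
  panel
}

#' Per-variant LD scores of a panel
#'
#' @param panel An `lderge_panel`.
#' @return Numeric vector of LD scores in panel variant order.
#' @export
panel_ld_scores <- function(panel) {
  unlist(lapply(panel$blocks, function(b) b$ld_scores), use.names = FALSE)
}
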