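# Reading and writing summary statistics and results. Tab-delimited,
# UTF-8, '.' decimal, "NA" for missing — fixed so outputs stay diff-able.

SUMSTATS_COLS <- c("CHR", "ID", "POS", "A1", "A2", "N", "BETA_INT", "SE_INT", "Z_INT")

#' Read GWIS summary statistics
#'
#' Parses the tab-delimited interaction summary-statistic dialect
#' (header columns `CHR, ID, POS, A1, A2, N` plus `Z_INT` or
#' `BETA_INT` + `SE_INT`; the Z-score is recomputed from `BETA/SE` when
#' absent). Lower-case headers as written by [write_sumstats()] are also
#' accepted.
#'
#' @param path File path.
#' @return Summary-statistics tibble with columns `chrom`, `id`, `pos`,
#'   `a1`, `a2`, `n`, `beta_int`, `se_int`, `z_int`.
#' @export
read_sumstats <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = "NA", comment = "#")
  names(df) <- toupper(names(df))
  names(df)[names(df) == "CHROM"] <- "CHR"
  required <- c("ID", "A1", "A2", "N")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  has_z <- "Z_INT" %in% names(df)
  has_beta <- all(c("BETA_INT", "SE_INT") %in% names(df))
  if (!has_z && !has_beta) {
    abort("need either Z_INT or both BETA_INT and SE_INT")
  }
  if (anyDuplicated(df$ID)) {
    dup <- which(duplicated(df$ID))
    abort(sprintf("duplicate variant ID(s) at line(s): %s",
                  paste(head(dup + 1L, 5), collapse = ", ")))
  }
  z <- if (has_z) df$Z_INT else df$BETA_INT / df$SE_INT
  if (!is.numeric(z) || anyNA(z)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(z))))
    abort(sprintf("non-numeric or missing Z at line(s): %s",
                  paste(head(bad + 1L, 5), collapse = ", ")))
  }
  n_rat <- max(df$N) / min(df$N)
  if (n_rat >= 1.1) {
    warn(sprintf("per-variant N varies by a factor of %.2f; the minimum is conservative", n_rat))
  }
  inform(sprintf("read %d variant records from %s", nrow(df), path))
  tibble::tibble(
    chrom = as.character(df$CHR %||% NA_character_), id = as.character(df$ID),
    pos = as.integer(df$POS %||% NA_integer_),
    a1 = as.character(df$A1), a2 = as.character(df$A2), n = as.integer(df$N),
    beta_int = if (has_beta) df$BETA_INT else z / sqrt(df$N),
    se_int = if (has_beta) df$SE_INT else 1 / sqrt(df$N),
    z_int = as.numeric(z)
  )
}

#' Write GWIS summary statistics
#'
#' @param stats Summary-statistics tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  out <- tibble::tibble(
    CHR = stats$chrom, ID = stats$id, POS = stats$pos,
    A1 = stats$a1, A2 = stats$a2, N = stats$n,
    BETA_INT = stats$beta_int, SE_INT = stats$se_int, Z_INT = stats$z_int
  )
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

result_fields <- function(result) {
  if (inherits(result, "lderge_fit")) {
    list(kind = "fit", glance = as.list(glance(result)),
         leave_one_out = result$leave_one_out)
  } else if (inherits(result, "lderge_aggregate")) {
    list(kind = "aggregate", glance = as.list(glance(result)),
         per_covariate = as.data.frame(result$per_covariate))
  } else {
    abort("result must be an lderge_fit or lderge_aggregate")
  }
}

#' Write / read an estimation result
#'
#' Writes twin outputs: `<path>.json` with every numeric field at full
#' double precision (so p-values such as 1e-24 survive a round trip) and
#' `<path>.tsv` with the glance table for spreadsheet use. An optional
#' provenance record (seed, package version) is embedded in the JSON.
#'
#' @param result An `lderge_fit` or `lderge_aggregate`.
#' @param path Output path prefix (extensions are appended).
#' @param seed Optional seed to record in the provenance header.
#' @return `write_results()` returns the JSON path invisibly;
#'   `read_results()` returns the parsed result as a list with a `glance`
#'   tibble.
#' @export
write_results <- function(result, path, seed = NULL) {
  payload <- result_fields(result)
  payload$provenance <- list(
    package = "lderge",
    version = as.character(utils::packageVersion("lderge")),
    seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  json_path <- paste0(path, ".json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  gl <- tibble::as_tibble(payload$glance)
  readr::write_tsv(gl, paste0(path, ".tsv"), na = "NA", progress = FALSE)
  invisible(json_path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  json_path <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  payload$glance <- tibble::as_tibble(payload$glance)
  if (!is.null(payload$per_covariate)) {
    payload$per_covariate <- tibble::as_tibble(payload$per_covariate)
  }
  payload
}
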