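#' Missingness filter on raw RPKM values
#'
#' RPKM values below `rpkm_floor` are treated as missing.  Rows (RNAs) whose
#' missing fraction exceeds `max_missing` are dropped; surviving rows keep
#' their missing entries flagged as `NA` for the imputation performed by
#' [log2_transform()].
#'
#' The published filter drops RNAs "missing in more than 20 of the samples",
#' which is ambiguous between an absolute count and a percentage.  The
#' default interprets it as a fraction (cohort sizes differ widely, so a
#' fraction generalizes); `mode = "count"` applies an absolute-count cutoff.
#'
#' @param m an [expr_matrix()] on the raw RPKM scale.
#' @param rpkm_floor detection floor, default 0.05 RPKM.
#' @param max_missing maximum tolerated missingness per row: a fraction in
#'   `[0, 1]` when `mode = "fraction"` (default 0.20), an absolute sample
#'   count when `mode = "count"`.
#' @param mode `"fraction"` or `"count"`.
#' @return the filtered [expr_matrix()], missing entries set to `NA`.  An
#'   empty result (all rows dropped) is returned as a 0-row matrix, not an
#'   error.
#' @export
missingness_filter <- function(m, rpkm_floor = 0.05, max_missing = 0.20,
                               mode = c("fraction", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "rpkm")
    stop_sponge("missingness_filter expects raw RPKM values", "invalid_input")
  vals <- m$values
  vals[vals < rpkm_floor] <- NA_real_
  n_missing <- rowSums(is.na(vals))
  limit <- if (mode == "fraction") max_missing * ncol(vals) else max_missing
  keep <- n_missing <= limit
  out <- m
  out$values <- vals[keep, , drop = FALSE]
  out$rna_class <- m$rna_class[keep]
  out
}

#' Log2-transform with floor imputation
#'
#' Missing entries left by [missingness_filter()] are imputed at the
#' detection floor, then every entry is replaced by its log2.
#'
#' @param m an [expr_matrix()] on the RPKM scale (post missingness filter).
#' @param rpkm_floor imputation value for missing entries.
#' @return the [expr_matrix()] on the log2 scale.
#' @export
log2_transform <- function(m, rpkm_floor = 0.05) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "rpkm")
    stop_sponge("matrix is already log2-transformed", "invalid_input")
  vals <- m$values
  vals[is.na(vals)] <- rpkm_floor
  if (any(vals <= 0))
    stop_sponge("non-positive expression values cannot be log2-transformed",
                "invalid_input")
  out <- m
  out$values <- log2(vals)
  out$scale <- "log2"
  out
}

#' Variance filter by median absolute deviation
#'
#' Removes rows whose MAD — the *unscaled* median of absolute deviations
#' from the row median, no 1.4826 consistency constant — falls below
#' `min_mad` (log2 units).  Set `scaled = TRUE` for the normal-consistent
#' estimator.
#'
#' @param m an [expr_matrix()] on the log2 scale.
#' @param min_mad minimum MAD, default 0.5.
#' @param scaled apply the 1.4826 consistency constant (default `FALSE`).
#' @return the filtered [expr_matrix()].
#' @export
mad_filter <- function(m, min_mad = 0.5, scaled = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2")
    stop_sponge("mad_filter expects log2-scale values", "invalid_input")
  const <- if (scaled) 1.4826 else 1
  mads <- apply(m$values, 1L, function(r) const * median(abs(r - median(r))))
  keep <- mads >= min_mad
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out$rna_class <- m$rna_class[keep]
  out
}

#' Full expression preprocessing
#'
#' [missingness_filter()] then [log2_transform()] then [mad_filter()],
#' applied to one cohort (run it per subtype).  Idempotent on its own
#' output in the sense that re-filtering a preprocessed matrix removes
#' nothing further.
#'
#' @param m an [expr_matrix()] on the raw RPKM scale.
#' @inheritParams missingness_filter
#' @inheritParams mad_filter
#' @return the preprocessed log2-scale [expr_matrix()].
#' @export
preprocess_expression <- function(m, rpkm_floor = 0.05, max_missing = 0.20,
                                  mode = "fraction", min_mad = 0.5) {
  m <- missingness_filter(m, rpkm_floor, max_missing, mode)
  m <- log2_transform(m, rpkm_floor)
  mad_filter(m, min_mad)
}
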