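#' Spearman rank correlation with large-sample p-value
#'
#' Pearson correlation of average ranks (ties receive mean rank); two-sided
#' p-value from the t-approximation with `n - 2` degrees of freedom,
#' appropriate at the cohort sizes this screen is used on.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (length(y) != n || n < 3)
    stop_sponge("x and y must have equal length >= 3", "invalid_input")
  if (sd(x) == 0 || sd(y) == 0)
    stop_sponge("Spearman correlation undefined for a constant vector",
                "degenerate_correlation")
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(tstat), n - 2),
              greater   = pt(tstat, n - 2, lower.tail = FALSE),
              less      = pt(tstat, n - 2))
  list(rho = rho, p = min(p, 1))
}

#' First-order partial correlation
#'
#' The correlation between X and Y after removing the part explained by Z:
#' `(rho_xy - rho_xz * rho_yz) / (sqrt(1 - rho_xz^2) * sqrt(1 - rho_yz^2))`.
#' Applied to Spearman correlations this is the Spearman partial rank
#' correlation used by the screen.
#'
#' @param rho_xy,rho_xz,rho_yz pairwise correlations.
#' @return the partial correlation `rho_xy_given_z`.
#' @export
partial_spearman <- function(rho_xy, rho_xz, rho_yz) {
  if (any(abs(c(rho_xz, rho_yz)) >= 1))
    stop_sponge("|rho_xz| or |rho_yz| = 1: conditioning is degenerate",
                "degenerate_conditioning")
  (rho_xy - rho_xz * rho_yz) / (sqrt(1 - rho_xz^2) * sqrt(1 - rho_yz^2))
}

#' Sensitivity of a correlation to a miRNA
#'
#' How much of the lncRNA-mRNA correlation is carried by the miRNA:
#' `S_Z = rho_xy - rho_xy_given_z`.  Large positive values implicate the
#' miRNA in the association.
#'
#' @param rho_xy marginal Spearman correlation.
#' @param rho_xy_given_z partial correlation given the miRNA.
#' @return the sensitivity score.
#' @export
sensitivity <- function(rho_xy, rho_xy_given_z) rho_xy - rho_xy_given_z

#' Partial-correlation screen over all lncRNA:miRNA:mRNA triplets
#'
#' Enumerates every lncRNA x mRNA pair; pairs with Spearman
#' `rho_xy > rho_min` and p-value `< p_max` are retained as strongly
#' positively correlated.  For each retained pair, every miRNA is evaluated:
#' the partial correlation given the miRNA and the sensitivity score
#' `S_Z` are computed, and `passes_threshold` flags triplets with
#' `S_Z >= t`.  The screen is exhaustive over the retained triplet space; no
#' multiple-testing correction is applied at this stage (`bh = TRUE`
#' switches the pair p-values to Benjamini-Hochberg adjusted ones).
#'
#' @param m a preprocessed (log2) [expr_matrix()] containing all three RNA
#'   classes.
#' @param t sensitivity threshold (the study reports both 0.2 and 0.3).
#' @param rho_min minimum lncRNA-mRNA Spearman correlation (default 0.5).
#' @param p_max maximum pair p-value (default 0.05).
#' @param bh apply Benjamini-Hochberg adjustment to pair p-values.
#' @return data.frame of correlation records: `lncrna`, `mirna`, `mrna`,
#'   `rho_xy`, `rho_xy_p`, `rho_xz`, `rho_yz`, `rho_xy_given_z`, `s_z`,
#'   `passes_threshold`.
#' @export
screen_candidates <- function(m, t = 0.2, rho_min = 0.5, p_max = 0.05,
                              bh = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  lnc <- class_rows(m, "lncRNA")
  mir <- class_rows(m, "miRNA")
  mrna <- class_rows(m, "mRNA")
  if (nrow(lnc) == 0 || nrow(mir) == 0 || nrow(mrna) == 0)
    stop_sponge("screen needs lncRNA, miRNA and mRNA rows in the matrix",
                "invalid_config")
  n <- ncol(m$values)
  rk <- function(mat) t(apply(mat, 1L, rank))
  rl <- rk(lnc); rg <- rk(mrna); rz <- rk(mir)
  # Pearson on average ranks == Spearman with midranks
  rho_lg <- cor(t(rl), t(rg))
  tstat <- rho_lg * sqrt((n - 2) / pmax(1 - rho_lg^2, .Machine$double.eps))
  p_lg <- 2 * pt(-abs(tstat), n - 2)
  if (bh) p_lg[] <- stats::p.adjust(p_lg, "BH")
  keep <- which(rho_lg > rho_min & p_lg < p_max, arr.ind = TRUE)
  if (nrow(keep) == 0) return(empty_screen_result())
  rho_lz <- cor(t(rl), t(rz))   # lncRNA x miRNA
  rho_gz <- cor(t(rg), t(rz))   # mRNA x miRNA
  n_mir <- nrow(mir)
  recs <- vector("list", nrow(keep))
  for (k in seq_len(nrow(keep))) {
    i <- keep[k, 1]; j <- keep[k, 2]
    xz <- rho_lz[i, ]; yz <- rho_gz[j, ]
    pxy <- (rho_lg[i, j] - xz * yz) /
      (sqrt(pmax(1 - xz^2, .Machine$double.eps)) *
         sqrt(pmax(1 - yz^2, .Machine$double.eps)))
    s <- rho_lg[i, j] - pxy
    recs[[k]] <- data.frame(
      lncrna = rownames(lnc)[i], mirna = rownames(mir), mrna = rownames(mrna)[j],
      rho_xy = rho_lg[i, j], rho_xy_p = p_lg[i, j],
      rho_xz = xz, rho_yz = yz, rho_xy_given_z = pxy, s_z = s,
      passes_threshold = s >= t, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "t") <- t
  out
}

empty_screen_result <- function() {
  out <- data.frame(lncrna = character(), mirna = character(),
                    mrna = character(), rho_xy = numeric(),
                    rho_xy_p = numeric(), rho_xz = numeric(),
                    rho_yz = numeric(), rho_xy_given_z = numeric(),
                    s_z = numeric(), passes_threshold = logical(),
                    stringsAsFactors = FALSE)
  out
}
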