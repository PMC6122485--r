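#' Candidate expression cutoffs for up/down-regulation calls
#'
#' The six candidate cutoffs are the 10th and 90th percentiles, the lower
#' and upper quartiles, the mean and the median.  Percentiles use the
#' linear-interpolation convention (R quantile type 7).  Duplicates (e.g.
#' mean = median on symmetric data) are retained with distinct labels.
#'
#' @param values numeric expression vector (>= 20 values).
#' @return data.frame with `label` and `cutoff`.
#' @export
candidate_cutoffs <- function(values) {
  if (length(values) < 20)
    stop_sponge("need >= 20 values to place cutoffs", "invalid_input")
  if (sd(values) == 0)
    stop_sponge("constant expression vector: cutoffs are degenerate",
                "degenerate_cutoff")
  q <- quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                type = 7)
  data.frame(label = c("P10", "Q1", "median", "mean", "Q3", "P90"),
             cutoff = c(q[1], q[2], q[3], mean(values), q[4], q[5]),
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-squared statistic.  Backed by
#' [survival::survdiff()]; degenerate inputs (no events at all) return
#' statistic 0 and p = 1 rather than erroring, so sweeping over many
#' candidate splits stays robust.
#'
#' @param groupA,groupB data.frames with `time` and `event` columns.
#' @return list with `statistic` and `p`.
#' @export
logrank <- function(groupA, groupB) {
  if (nrow(groupA) == 0 || nrow(groupB) == 0)
    stop_sponge("both groups must be non-empty", "invalid_input")
  time <- c(groupA$time, groupB$time)
  event <- c(groupA$event, groupB$event)
  grp <- rep(c(0L, 1L), c(nrow(groupA), nrow(groupB)))
  if (sum(event) == 0) return(list(statistic = 0, p = 1))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd_$chisq),
       p = pchisq(unname(sd_$chisq), df = 1, lower.tail = FALSE))
}

#' Select the most prognostic cutoff for one RNA
#'
#' Splits patients at each candidate cutoff (`> cutoff` up-regulated,
#' `<= cutoff` down-regulated), keeps splits where both sides have more
#' than `min_group` patients, and returns the cutoff whose log-rank
#' p-value is smallest (with that p-value).
#'
#' @param values per-patient expression, aligned with `survival_df`.
#' @param survival_df data.frame with `time`, `event` (rows = patients in
#'   the same order as `values`).
#' @param min_group both sides of a valid split must exceed this size
#'   (default 10).
#' @return list with `label`, `cutoff`, `p`; or `NULL` when no valid
#'   split exists.
#' @export
select_cutoff <- function(values, survival_df, min_group = 10) {
  stopifnot(length(values) == nrow(survival_df))
  cand <- candidate_cutoffs(values)
  best <- NULL
  for (k in seq_len(nrow(cand))) {
    up <- values > cand$cutoff[k]
    if (sum(up) <= min_group || sum(!up) <= min_group) next
    lr <- logrank(survival_df[up, , drop = FALSE],
                  survival_df[!up, , drop = FALSE])
    if (is.null(best) || lr$p < best$p)
      best <- list(label = cand$label[k], cutoff = cand$cutoff[k], p = lr$p)
  }
  best
}

#' Split patients by a triplet expression pattern
#'
#' The up-down-up group contains patients with lncRNA above its cutoff,
#' miRNA at or below its cutoff and mRNA above its cutoff; down-up-down
#' reverses all three inequalities.  The complement is everyone else.
#' Ties sit on the "down" side (`<= cutoff` is down-regulated).
#'
#' @param lnc,mir,mrna per-patient expression vectors.
#' @param cut_lnc,cut_mir,cut_mrna selected cutoffs.
#' @param pattern `"up-down-up"` or `"down-up-down"`.
#' @return logical vector: `TRUE` for pattern-group membership.
#' @export
pattern_groups <- function(lnc, mir, mrna, cut_lnc, cut_mir, cut_mrna,
                           pattern = c("up-down-up", "down-up-down")) {
  pattern <- match.arg(pattern)
  if (pattern == "up-down-up") {
    lnc > cut_lnc & mir <= cut_mir & mrna > cut_mrna
  } else {
    lnc <= cut_lnc & mir > cut_mir & mrna <= cut_mrna
  }
}

#' Evaluate one triplet for prognostic value
#'
#' Per-RNA cutoffs are selected by single-RNA log-rank optimality
#' ([select_cutoff()]) and reused both for the triplet pattern groups and
#' for the single-RNA exclusion test, keeping the two stages consistent.
#' For each pattern the patients are split into pattern vs complement;
#' splits with a side of 10 or fewer patients are not evaluable.  The
#' triplet is *prognostic* iff the best pattern's log-rank p (`p_xyz`) is
#' below `alpha` while every single-RNA p is at least `alpha`.  The
#' f-score is the log-fold decrease
#' `-log(p_xyz / min(p_x, p_y, p_z))`, base 10 by default ("orders of
#' magnitude"), so any prognostic verdict forces `f_score > 0`.
#'
#' @param triplet list or one-row data.frame with `lncrna`, `mirna`,
#'   `mrna` ids.
#' @param expr a log2-scale [expr_matrix()] containing those RNAs.
#' @param survival_df data.frame `patient`, `time`, `event`; patients are
#'   matched to the expression columns by id.
#' @param alpha significance level (default 0.05, uncorrected as in the
#'   original screen).
#' @param min_group group-size rule: both groups must have more than this
#'   many patients (default 10).
#' @param log_base base of the f-score logarithm (default 10).
#' @return a one-row data.frame (`prognostic_result`): ids, `pattern`,
#'   per-RNA cutoff labels, `n_pattern`, `n_rest`, `p_xyz`, `p_x`, `p_y`,
#'   `p_z`, `f_score`, `verdict` in
#'   `prognostic` / `not_prognostic` / `not_evaluable`.
#' @export
evaluate_triplet <- function(triplet, expr, survival_df, alpha = 0.05,
                             min_group = 10, log_base = 10) {
  stopifnot(inherits(expr, "expr_matrix"))
  ids <- c(lncrna = triplet$lncrna[1], mirna = triplet$mirna[1],
           mrna = triplet$mrna[1])
  idx <- match(survival_df$patient, colnames(expr$values))
  if (anyNA(idx))
    stop_sponge("survival patients missing from expression matrix",
                "invalid_input")
  v <- expr$values[, idx, drop = FALSE]
  surv <- survival_df[, c("time", "event")]

  base_row <- data.frame(
    lncrna = ids[["lncrna"]], mirna = ids[["mirna"]], mrna = ids[["mrna"]],
    pattern = NA_character_, cut_lnc = NA_character_,
    cut_mir = NA_character_, cut_mrna = NA_character_,
    n_pattern = NA_integer_, n_rest = NA_integer_,
    p_xyz = NA_real_, p_x = NA_real_, p_y = NA_real_, p_z = NA_real_,
    f_score = NA_real_, verdict = "not_evaluable",
    stringsAsFactors = FALSE)

  cuts <- lapply(ids, function(id) {
    if (!id %in% rownames(v)) return(NULL)
    select_cutoff(v[id, ], surv, min_group)
  })
  if (any(vapply(cuts, is.null, logical(1)))) return(base_row)

  best <- NULL
  for (pat in c("up-down-up", "down-up-down")) {
    in_pat <- pattern_groups(v[ids[["lncrna"]], ], v[ids[["mirna"]], ],
                             v[ids[["mrna"]], ],
                             cuts$lncrna$cutoff, cuts$mirna$cutoff,
                             cuts$mrna$cutoff, pat)
    if (sum(in_pat) <= min_group || sum(!in_pat) <= min_group) next
    lr <- logrank(surv[in_pat, , drop = FALSE], surv[!in_pat, , drop = FALSE])
    if (is.null(best) || lr$p < best$p)
      best <- list(pattern = pat, p = lr$p, n_pattern = sum(in_pat),
                   n_rest = sum(!in_pat))
  }
  if (is.null(best)) return(base_row)

  p_singles <- c(cuts$lncrna$p, cuts$mirna$p, cuts$mrna$p)
  f <- -log(best$p / min(p_singles), base = log_base)
  verdict <- if (best$p < alpha && min(p_singles) >= alpha) "prognostic"
  else "not_prognostic"
  out <- base_row
  out$pattern <- best$pattern
  out$cut_lnc <- cuts$lncrna$label
  out$cut_mir <- cuts$mirna$label
  out$cut_mrna <- cuts$mrna$label
  out$n_pattern <- best$n_pattern
  out$n_rest <- best$n_rest
  out$p_xyz <- best$p
  out$p_x <- cuts$lncrna$p
  out$p_y <- cuts$mrna$p
  out$p_z <- cuts$mirna$p
  out$f_score <- f
  out$verdict <- verdict
  out
}

#' Evaluate many triplets and rank by f-score
#'
#' @param triplets data.frame with `lncrna`, `mirna`, `mrna`.
#' @inheritParams evaluate_triplet
#' @return data.frame of `prognostic_result` rows ranked by decreasing
#'   `f_score` (non-evaluable rows last).
#' @export
prognostic_screen <- function(triplets, expr, survival_df, alpha = 0.05,
                              min_group = 10, log_base = 10) {
  rows <- lapply(seq_len(nrow(triplets)), function(i)
    evaluate_triplet(triplets[i, , drop = FALSE], expr, survival_df,
                     alpha, min_group, log_base))
  out <- do.call(rbind, rows)
  out <- out[order(out$f_score, decreasing = TRUE, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
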