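#' Run configuration for the end-to-end pipeline
#'
#' @param t sensitivity-score threshold (default 0.2; the study also
#'   reports 0.3).
#' @param rho_min minimum lncRNA-mRNA Spearman correlation (0.5).
#' @param screen_p maximum pair p-value at the screen (0.05).
#' @param kci a [kernel_config()]; its `alpha` (0.01) governs both kernel
#'   tests.
#' @param prognostic_alpha log-rank significance level (0.05).
#' @param min_group survival group-size rule (both groups > 10).
#' @param min_sources minimum target-database sources per side (1).
#' @param seed run seed; every stochastic stage derives its own stream
#'   from it.
#' @return a `run_config` list.
#' @export
run_config <- function(t = 0.2, rho_min = 0.5, screen_p = 0.05,
                       kci = kernel_config(), prognostic_alpha = 0.05,
                       min_group = 10, min_sources = 1, seed = 1) {
  if (t <= 0 || t >= 2) stop_sponge("t must be in (0, 2)", "invalid_config")
  for (nm in c("rho_min", "screen_p", "prognostic_alpha")) {
    v <- get(nm)
    if (v <= 0 || v >= 1)
      stop_sponge(sprintf("`%s` must be in (0, 1)", nm), "invalid_config")
  }
  kci$seed <- derive_seed(seed, "kci")
  structure(list(t = t, rho_min = rho_min, screen_p = screen_p, kci = kci,
                 prognostic_alpha = prognostic_alpha, min_group = min_group,
                 min_sources = min_sources, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full discovery pipeline on one cohort
#'
#' preprocess -> partial-correlation screen -> kernel independence tests ->
#' target-database filter -> prognostic evaluation (when survival data are
#' supplied) -> network/cluster/proximity annotation (when locations are
#' supplied).
#'
#' @param expr an [expr_matrix()] on the raw RPKM scale.
#' @param target_db a `target_db` (or data.frame in the target schema).
#' @param cfg a [run_config()].
#' @param survival_df optional survival data.frame (`patient`, `time`,
#'   `event`).
#' @param locations optional gene locations (see [proximal_triplets()]).
#' @return a `subtype_result` list: `triplets` (final set with all
#'   statistics), `prognostic`, `network`, `clusters`, `proximal`, and
#'   `counts` — the RNAs/candidates surviving each step.
#' @export
run_subtype <- function(expr, target_db, cfg = run_config(),
                        survival_df = NULL, locations = NULL) {
  if (!inherits(target_db, "target_db") && is.data.frame(target_db))
    target_db <- as_target_db(target_db)
  pre <- preprocess_expression(expr)
  screened <- screen_candidates(pre, t = cfg$t, rho_min = cfg$rho_min,
                                p_max = cfg$screen_p)
  n_pass <- sum(screened$passes_threshold)
  confirmed <- confirm_triplets(screened, pre, cfg$kci)
  filtered <- filter_by_support(confirmed, target_db, cfg$min_sources)
  prognostic <- NULL
  n_prog <- NA_integer_
  if (!is.null(survival_df) && nrow(filtered) > 0) {
    prognostic <- prognostic_screen(filtered, pre, survival_df,
                                    alpha = cfg$prognostic_alpha,
                                    min_group = cfg$min_group)
    n_prog <- sum(prognostic$verdict == "prognostic")
  }
  network <- export_network(filtered)
  clusters <- if (nrow(filtered) > 0) cluster_by_pair(filtered, pre) else NULL
  proximal <- if (!is.null(locations) && nrow(filtered) > 0)
    proximal_triplets(filtered, locations) else NULL
  structure(list(
    subtype = expr$subtype, triplets = filtered, prognostic = prognostic,
    network = network, clusters = clusters, proximal = proximal,
    counts = c(rna_after_preprocess = nrow(pre$values),
               screen = n_pass, kci = nrow(confirmed),
               target_filter = nrow(filtered), prognostic = n_prog),
    config = cfg), class = "subtype_result")
}

#' Run the pipeline over several cohorts and assemble a run report
#'
#' Cohorts are processed independently; an error in one cohort is logged
#' in the report and the remaining cohorts still run.  The report also
#' tabulates the overlap of discovered triplets across cohorts (exact
#' (lncRNA, miRNA, mRNA) identity).
#'
#' @param cohorts named list; each element is a list with `expr` and
#'   optionally `survival`, `locations`.
#' @param target_db shared target database.
#' @param cfg a [run_config()].
#' @return a `run_report`: per-cohort `results`, `counts` matrix,
#'   `overlap` table, `errors`, the echoed `config` and package version.
#' @export
run_all <- function(cohorts, target_db, cfg = run_config()) {
  results <- list()
  errors <- list()
  for (nm in names(cohorts)) {
    res <- tryCatch(
      run_subtype(cohorts[[nm]]$expr, target_db, cfg,
                  survival_df = cohorts[[nm]]$survival,
                  locations = cohorts[[nm]]$locations),
      error = function(e) e)
    if (inherits(res, "error")) errors[[nm]] <- conditionMessage(res)
    else results[[nm]] <- res
  }
  counts <- do.call(rbind, lapply(results, `[[`, "counts"))
  trip_ids <- lapply(results, function(r)
    if (nrow(r$triplets)) paste(r$triplets$lncrna, r$triplets$mirna,
                                r$triplets$mrna) else character(0))
  all_ids <- unique(unlist(trip_ids))
  overlap <- if (length(all_ids)) {
    mem <- vapply(trip_ids, function(s) all_ids %in% s,
                  logical(length(all_ids)))
    mem <- matrix(mem, nrow = length(all_ids),
                  dimnames = list(all_ids, names(results)))
    as.data.frame(table(n_subtypes = rowSums(mem)))
  } else data.frame(n_subtypes = integer(), Freq = integer())
  structure(list(results = results, counts = counts, overlap = overlap,
                 errors = errors, config = cfg,
                 version = as.character(utils::packageVersion("spongescout"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> spongescout", x$version, "\n")
  cat("  t =", x$config$t, " seed =", x$config$seed, "\n")
  if (!is.null(x$counts)) {
    cat("  survivors per step:\n")
    print(x$counts)
  }
  if (length(x$errors)) {
    cat("  failed cohorts:\n")
    for (nm in names(x$errors)) cat("   ", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}

#' Write the per-cohort pipeline outputs as TSV files
#'
#' Every file carries a header comment echoing the thresholds so results
#' stay attributable to their parameters.
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return invisibly, the output directory.
#' @export
write_run_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# spongescout %s | t=%g rho_min=%g screen_p=%g alpha=%g seed=%d",
                 report$version, report$config$t, report$config$rho_min,
                 report$config$screen_p, report$config$kci$alpha,
                 report$config$seed)
  wr <- function(df, path) {
    con <- file(path, "w")
    writeLines(hdr, con)
    close(con)
    data.table::fwrite(df, path, sep = "\t", append = TRUE,
                       col.names = TRUE)
  }
  for (nm in names(report$results)) {
    r <- report$results[[nm]]
    wr(r$triplets, file.path(dir, paste0(nm, "_triplets.tsv")))
    if (!is.null(r$prognostic))
      wr(r$prognostic, file.path(dir, paste0(nm, "_prognostic.tsv")))
    if (!is.null(r$clusters))
      wr(r$clusters, file.path(dir, paste0(nm, "_clusters.tsv")))
    if (!is.null(r$proximal))
      wr(r$proximal, file.path(dir, paste0(nm, "_proximal.tsv")))
    write_network_files(r$network, dir, paste0(nm, "_network"))
  }
  if (!is.null(report$counts))
    wr(as.data.frame(report$counts), file.path(dir, "step_counts.tsv"))
  wr(report$overlap, file.path(dir, "subtype_overlap.tsv"))
  invisible(dir)
}
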