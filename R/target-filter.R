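#' Load miRNA-target databases from TSV files
#'
#' Each file must have columns `mirna`, `target`, `target_class`
#' (`lncRNA`/`mRNA`), `source`, `evidence` (`P` predicted / `E`
#' experimental).  Files are unioned with provenance preserved: the same
#' pair reported by two sources yields two rows.  Exact duplicate
#' (mirna, target, source) rows are collapsed.
#'
#' miRNA identifiers are matched exactly after lowercasing; `-5p`/`-3p`
#' arm suffixes are *not* stripped (arm identity matters biologically).
#' Supply `id_map` (named character vector old -> new) to normalize real
#' database identifiers before matching.
#'
#' @param files character vector of TSV paths.
#' @param id_map optional named character vector remapping miRNA ids.
#' @return a `target_db` data.frame.
#' @export
load_targets <- function(files, id_map = NULL) {
  cols <- c("mirna", "target", "target_class", "source", "evidence")
  parts <- lapply(files, function(f) {
    dt <- as.data.frame(data.table::fread(f, sep = "\t",
                                          colClasses = "character"))
    missing_cols <- setdiff(cols, names(dt))
    if (length(missing_cols))
      stop_sponge(sprintf("%s: missing column(s) %s", f,
                          paste(missing_cols, collapse = ", ")),
                  "malformed_target_db")
    bad <- which(!dt$target_class %in% c("lncRNA", "mRNA"))
    if (length(bad))
      stop_sponge(sprintf("%s: unknown target_class at data line %d (%s)",
                          f, bad[1], dt$target_class[bad[1]]),
                  "malformed_target_db")
    bad_ev <- which(!dt$evidence %in% c("P", "E"))
    if (length(bad_ev))
      stop_sponge(sprintf("%s: evidence must be P or E at data line %d",
                          f, bad_ev[1]), "malformed_target_db")
    dt[cols]
  })
  db <- if (length(parts)) do.call(rbind, parts) else
    as.data.frame(setNames(rep(list(character()), 5), cols))
  db$mirna <- tolower(db$mirna)
  if (!is.null(id_map)) {
    hit <- db$mirna %in% names(id_map)
    db$mirna[hit] <- unname(id_map[db$mirna[hit]])
  }
  db <- unique(db)
  rownames(db) <- NULL
  class(db) <- c("target_db", "data.frame")
  db
}

#' Coerce an in-memory pair table (e.g. from [simulate_target_db()]) to a
#' `target_db`
#'
#' @param pairs data.frame with the target TSV schema.
#' @return a `target_db`.
#' @export
as_target_db <- function(pairs) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  data.table::fwrite(pairs, f, sep = "\t")
  load_targets(f)
}

#' Filter candidate triplets by miRNA-target support
#'
#' A triplet is retained only if the target database supports the miRNA
#' targeting *both* the lncRNA and the mRNA, each with at least
#' `min_sources` distinct sources.  Retained rows are annotated with the
#' supporting source lists and per-side database counts, which downstream
#' prioritization can use.
#'
#' @param triplets data.frame with `lncrna`, `mirna`, `mrna` columns
#'   (e.g. from [confirm_triplets()]).
#' @param db a `target_db` from [load_targets()].
#' @param min_sources minimum distinct supporting sources per side
#'   (default 1).
#' @return the retained triplets with `lnc_support`, `mrna_support`
#'   (";"-separated source names), `n_support_lnc`, `n_support_mrna`.
#' @export
filter_by_support <- function(triplets, db, min_sources = 1) {
  if (nrow(triplets) == 0) {
    out <- cbind(triplets, lnc_support = character(0),
                 mrna_support = character(0),
                 n_support_lnc = integer(0), n_support_mrna = integer(0))
    return(out)
  }
  support <- function(mirna, target) {
    hit <- db$mirna == tolower(mirna) & db$target == target
    sort(unique(db$source[hit]))
  }
  lnc_src <- mapply(function(mi, tg) paste(support(mi, tg), collapse = ";"),
                    triplets$mirna, triplets$lncrna)
  mrna_src <- mapply(function(mi, tg) paste(support(mi, tg), collapse = ";"),
                     triplets$mirna, triplets$mrna)
  n_lnc <- ifelse(lnc_src == "", 0L,
                  lengths(strsplit(lnc_src, ";", fixed = TRUE)))
  n_mrna <- ifelse(mrna_src == "", 0L,
                   lengths(strsplit(mrna_src, ";", fixed = TRUE)))
  out <- triplets
  out$lnc_support <- unname(lnc_src)
  out$mrna_support <- unname(mrna_src)
  out$n_support_lnc <- as.integer(n_lnc)
  out$n_support_mrna <- as.integer(n_mrna)
  out <- out[out$n_support_lnc >= min_sources &
               out$n_support_mrna >= min_sources, , drop = FALSE]
  rownames(out) <- NULL
  out
}
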