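#' Expression matrix container
#'
#' A thin S3 container holding an RNAs-by-samples numeric matrix together with
#' the RNA class of every row (`lncRNA`, `miRNA` or `mRNA`), an optional
#' cohort/subtype label, and a scale tag recording whether values are raw
#' RPKM or log2 RPKM.  All pipeline stages consume and return this container.
#'
#' @param values numeric matrix, rows = RNAs (rownames required, unique),
#'   columns = samples (colnames required).
#' @param rna_class character vector, one of `"lncRNA"`, `"miRNA"`, `"mRNA"`
#'   per row of `values`.
#' @param subtype single cohort label (e.g. a PAM50 subtype or `"synthetic"`).
#' @param scale `"rpkm"` for raw values, `"log2"` after transformation.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, rna_class,
                        subtype = "synthetic", scale = c("rpkm", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_sponge("`values` must be a numeric matrix", "invalid_input")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_sponge("`values` needs row (RNA) and column (sample) names",
                "invalid_input")
  if (anyDuplicated(rownames(values)))
    stop_sponge("duplicate RNA ids", "invalid_input")
  rna_class <- as.character(rna_class)
  if (length(rna_class) != nrow(values))
    stop_sponge("`rna_class` must have one entry per row", "invalid_input")
  bad <- setdiff(unique(rna_class), c("lncRNA", "miRNA", "mRNA"))
  if (length(bad))
    stop_sponge(paste("unknown RNA class:", paste(bad, collapse = ", ")),
                "invalid_input")
  structure(list(values = values,
                 rna_class = setNames(rna_class, rownames(values)),
                 subtype = subtype, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(factor(x$rna_class, levels = c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf(
    "<expr_matrix> %d RNAs x %d samples [%s scale, subtype: %s]\n",
    nrow(x$values), ncol(x$values), x$scale, x$subtype))
  cat(sprintf("  lncRNA: %d  miRNA: %d  mRNA: %d\n",
              tab[["lncRNA"]], tab[["miRNA"]], tab[["mRNA"]]))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by RNA class
#'
#' @param m an [expr_matrix()].
#' @param class one of `"lncRNA"`, `"miRNA"`, `"mRNA"`.
#' @return the numeric submatrix of rows with that class.
#' @export
class_rows <- function(m, class) {
  m$values[m$rna_class == class, , drop = FALSE]
}

is_empty_result <- function(m) inherits(m, "expr_matrix") && nrow(m$values) == 0L

#' Write / read the expression TSV interchange format
#'
#' Layout: first column `rna`, second `class`, remaining columns one per
#' sample.  This is the format emitted by the simulator and consumed by
#' `spongescout preprocess`.
#'
#' @param m an [expr_matrix()].
#' @param path file path.
#' @return `read_expression_tsv` returns an [expr_matrix()];
#'   `write_expression_tsv` returns `path` invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  dt <- data.table::data.table(rna = rownames(m$values),
                               class = unname(m$rna_class))
  dt <- cbind(dt, data.table::as.data.table(m$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param subtype,scale passed to [expr_matrix()].
#' @export
read_expression_tsv <- function(path, subtype = "synthetic",
                                scale = c("rpkm", "log2")) {
  dt <- data.table::fread(path, sep = "\t")
  if (!all(c("rna", "class") %in% names(dt)))
    stop_sponge("expression TSV needs `rna` and `class` columns",
                "invalid_input")
  vals <- as.matrix(dt[, setdiff(names(dt), c("rna", "class")),
                       with = FALSE])
  rownames(vals) <- dt$rna
  expr_matrix(vals, dt$class, subtype = subtype, scale = match.arg(scale))
}

#' Read / write the survival TSV (`patient`, `time`, `event`)
#'
#' @param surv data.frame with columns `patient`, `time`, `event`.
#' @param path file path.
#' @export
write_survival_tsv <- function(surv, path) {
  stopifnot(all(c("patient", "time", "event") %in% names(surv)))
  data.table::fwrite(surv[, c("patient", "time", "event")], path, sep = "\t")
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!all(c("patient", "time", "event") %in% names(dt)))
    stop_sponge("survival TSV needs `patient`, `time`, `event`",
                "invalid_input")
  if (any(dt$time < 0) || !all(dt$event %in% c(0, 1)))
    stop_sponge("survival records need time >= 0 and event in {0,1}",
                "invalid_input")
  dt
}
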