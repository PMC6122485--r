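#' Cluster the mRNAs sharing a lncRNA:miRNA pair
#'
#' If every pairwise correlation exceeds `threshold` the mRNAs form one
#' cluster outright.  Otherwise Ward agglomeration (Ward.D2 update) is run
#' on the distance `d = 1 - rho`, and the number of clusters is chosen by
#' Mojena's stopping rule with the Milligan-Cooper constant: the first
#' fusion stage `j` whose *next* height exceeds
#' `mean(heights) + c * sd(heights)` stops the agglomeration at `n - j`
#' clusters (no such stage: one cluster).
#'
#' @param corr symmetric mRNA x mRNA Spearman correlation matrix with unit
#'   diagonal (rownames = mRNA ids).
#' @param threshold all-correlated shortcut threshold (default 0.7).
#' @param mojena_c Mojena constant (default 1.25 per Milligan & Cooper).
#' @return list with `clusters` (named integer vector of cluster indices),
#'   `n_clusters`, `heights` (fusion heights, `NULL` for the shortcut
#'   path) and `method`.
#' @export
cluster_mrnas <- function(corr, threshold = 0.7, mojena_c = 1.25) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop_sponge("corr must be a square correlation matrix", "invalid_input")
  ids <- rownames(corr) %||% paste0("mRNA", seq_len(nrow(corr)))
  n <- nrow(corr)
  if (n == 1)
    return(list(clusters = setNames(1L, ids), n_clusters = 1L,
                heights = NULL, method = "singleton"))
  off <- corr[upper.tri(corr)]
  if (all(off > threshold))
    return(list(clusters = setNames(rep(1L, n), ids), n_clusters = 1L,
                heights = NULL, method = "all_correlated"))
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "ward.D2")
  h <- hc$height
  k <- 1L
  if (length(h) >= 2) {
    lim <- mean(h) + mojena_c * sd(h)
    stop_j <- which(h[-1] > lim)  # stage j such that height_{j+1} > limit
    if (length(stop_j)) k <- n - stop_j[1]
  }
  cl <- stats::cutree(hc, k = k)
  names(cl) <- ids
  list(clusters = cl, n_clusters = as.integer(k), heights = h,
       method = "ward_mojena")
}

#' Cluster mRNAs for every lncRNA:miRNA pair in a triplet set
#'
#' @param triplets data.frame with `lncrna`, `mirna`, `mrna`.
#' @param expr log2-scale [expr_matrix()] with the mRNAs.
#' @param threshold,mojena_c passed to [cluster_mrnas()].
#' @return data.frame `lncrna`, `mirna`, `mrna`, `cluster`.
#' @export
cluster_by_pair <- function(triplets, expr, threshold = 0.7,
                            mojena_c = 1.25) {
  key <- paste(triplets$lncrna, triplets$mirna)
  out <- lapply(unique(key), function(k) {
    sub <- triplets[key == k, , drop = FALSE]
    mrnas <- unique(sub$mrna)
    if (length(mrnas) == 1) {
      cl <- setNames(1L, mrnas)
    } else {
      rk <- t(apply(expr$values[mrnas, , drop = FALSE], 1L, rank))
      cl <- cluster_mrnas(cor(t(rk)), threshold, mojena_c)$clusters
    }
    data.frame(lncrna = sub$lncrna[1], mirna = sub$mirna[1],
               mrna = names(cl), cluster = unname(cl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read gene locations from a GTF file
#'
#' Uses `gene`-type features and the `gene_id` attribute.
#'
#' @param path GTF path.
#' @return data.frame `rna`, `chromosome`, `start`, `end`, `strand`.
#' @export
read_gtf_locations <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  data.frame(rna = gr$gene_id,
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

# Gap in bp between two 1-based inclusive intervals on the same chromosome:
# 0 when they overlap or touch, else the count of bases strictly between.
interval_gap <- function(s1, e1, s2, e2) {
  if (s2 > e1) s2 - e1 - 1 else if (s1 > e2) s1 - e2 - 1 else 0
}

#' Flag spatially proximal triplets
#'
#' For each triplet, each of the three member pairs is *proximal* when both
#' genes lie on the same chromosome with an interval gap of at most
#' `window` bp (inclusive boundary; overlapping genes have gap 0; strand
#' is ignored).  Members without a location are reported as unknown, never
#' dropped silently.
#'
#' @param triplets data.frame with `lncrna`, `mirna`, `mrna`.
#' @param locations data.frame `rna`, `chromosome`, `start`, `end` (e.g.
#'   from [read_gtf_locations()] or [simulate_annotation()]).
#' @param window maximum gap in bp (default 100000).
#' @return `triplets` augmented with `prox_lnc_mrna`, `prox_lnc_mir`,
#'   `prox_mir_mrna` (logical, `NA` = unknown), `n_proximal_pairs` and
#'   `location_missing`.
#' @export
proximal_triplets <- function(triplets, locations, window = 100000) {
  loc <- locations
  if (inherits(loc, "sponge_annotation")) loc <- loc$locations
  find <- function(id) {
    i <- match(id, loc$rna)
    if (is.na(i)) NULL else loc[i, ]
  }
  pair_prox <- function(a, b) {
    la <- find(a); lb <- find(b)
    if (is.null(la) || is.null(lb)) return(NA)
    la$chromosome == lb$chromosome &&
      interval_gap(la$start, la$end, lb$start, lb$end) <= window
  }
  out <- triplets
  out$prox_lnc_mrna <- mapply(pair_prox, triplets$lncrna, triplets$mrna)
  out$prox_lnc_mir <- mapply(pair_prox, triplets$lncrna, triplets$mirna)
  out$prox_mir_mrna <- mapply(pair_prox, triplets$mirna, triplets$mrna)
  prox <- cbind(out$prox_lnc_mrna, out$prox_lnc_mir, out$prox_mir_mrna)
  out$n_proximal_pairs <- rowSums(prox, na.rm = TRUE)
  out$location_missing <- rowSums(is.na(prox)) > 0
  out
}

#' Export network tables from a triplet list
#'
#' Produces the tables behind a sponge-network figure: a lncRNA-mRNA edge
#' table (the mediating miRNAs as an edge attribute, edge weight = number
#' of distinct mediating miRNAs), a node table with RNA class and degree,
#' and per-lncRNA / per-miRNA sponge-participation counts.
#'
#' @param triplets data.frame with `lncrna`, `mirna`, `mrna`.
#' @return list of data.frames: `edges`, `nodes`, `lncrna_counts`,
#'   `mirna_counts`.
#' @export
export_network <- function(triplets) {
  if (nrow(triplets) == 0) {
    return(list(
      edges = data.frame(lncrna = character(), mrna = character(),
                         mirnas = character(), weight = integer()),
      nodes = data.frame(id = character(), class = character(),
                         degree = integer()),
      lncrna_counts = data.frame(lncrna = character(),
                                 n_sponges = integer()),
      mirna_counts = data.frame(mirna = character(),
                                n_sponges = integer())))
  }
  key <- paste(triplets$lncrna, triplets$mrna, sep = "\r")
  agg <- lapply(split(triplets, key), function(sub) {
    data.frame(lncrna = sub$lncrna[1], mrna = sub$mrna[1],
               mirnas = paste(sort(unique(sub$mirna)), collapse = ";"),
               weight = length(unique(sub$mirna)),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, agg)
  rownames(edges) <- NULL
  deg <- c(table(edges$lncrna), table(edges$mrna))
  nodes <- data.frame(
    id = c(unique(edges$lncrna), unique(edges$mrna)),
    class = rep(c("lncRNA", "mRNA"),
                c(length(unique(edges$lncrna)),
                  length(unique(edges$mrna)))),
    stringsAsFactors = FALSE)
  nodes$degree <- as.integer(deg[nodes$id])
  cnt <- function(col) {
    tb <- table(triplets[[col]])
    df <- data.frame(names(tb), as.integer(tb), stringsAsFactors = FALSE)
    names(df) <- c(col, "n_sponges")
    df[order(-df$n_sponges), , drop = FALSE]
  }
  list(edges = edges, nodes = nodes,
       lncrna_counts = cnt("lncrna"), mirna_counts = cnt("mirna"))
}

#' Write network tables as SIF + TSV files
#'
#' @param network list from [export_network()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_network_files <- function(network, dir, prefix = "network") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sif <- file.path(dir, paste0(prefix, ".sif"))
  writeLines(sprintf("%s ceRNA %s", network$edges$lncrna,
                     network$edges$mrna), sif)
  paths <- c(sif)
  for (nm in c("edges", "nodes", "lncrna_counts", "mirna_counts")) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".tsv"))
    data.table::fwrite(network[[nm]], p, sep = "\t")
    paths <- c(paths, p)
  }
  invisible(paths)
}
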