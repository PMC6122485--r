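#' Simulation configuration for the synthetic ceRNA world
#'
#' The generator plants three kinds of lncRNA:miRNA:mRNA triplets:
#'
#' * **planted** sponge triplets: on the log2 scale the miRNA follows a
#'   standard normal around its baseline, and both the lncRNA and the mRNA are
#'   negatively coupled to it with slope `coupling_strength` plus independent
#'   Gaussian noise.  The lncRNA and mRNA are therefore positively correlated,
#'   both are negatively correlated with the miRNA, and they are conditionally
#'   independent given the miRNA — the signature the pipeline must recover.
#' * **confounded nulls**: same construction plus a direct lncRNA-to-mRNA term
#'   (the lncRNA's own noise, scaled by `coupling_strength`, is injected into
#'   the mRNA) so conditional independence given the miRNA fails.
#' * **independent nulls**: three mutually independent RNAs with matched
#'   marginal variance.
#'
#' Values are emitted on an RPKM-like positive scale (`2^log2value`); the
#' pipeline re-logs them.
#'
#' @param n_samples patients per cohort (>= 10).
#' @param n_planted,n_null_confounded,n_null_independent triplet counts (>= 1).
#' @param coupling_strength slope of the miRNA repression on the log2 scale.
#' @param noise_sd standard deviation of the per-RNA log2 noise.
#' @param hazard_ratio relative hazard between pattern-concordant and
#'   discordant patients (see [simulate_survival()]).
#' @param censor_rate fraction of patients censored.
#' @param decoy_rate probability that any non-interacting (miRNA, target) pair
#'   enters the simulated target database as a decoy.
#' @param n_prognostic number of planted triplets carrying a survival effect.
#' @param seed RNG seed; identical configs give bit-identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 200, n_planted = 20,
                       n_null_confounded = 50, n_null_independent = 50,
                       coupling_strength = 1, noise_sd = 0.3,
                       hazard_ratio = 3, censor_rate = 0.2,
                       decoy_rate = 0.1, n_prognostic = 1, seed = 1) {
  if (n_samples < 10)
    stop_sponge("n_samples < 10: downstream tests are meaningless",
                "invalid_config")
  for (nm in c("n_planted", "n_null_confounded", "n_null_independent")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 1 || v != round(v))
      stop_sponge(sprintf("`%s` must be a positive integer", nm),
                  "invalid_config")
  }
  if (noise_sd <= 0) stop_sponge("noise_sd must be > 0", "invalid_config")
  if (hazard_ratio <= 0) stop_sponge("hazard_ratio must be > 0",
                                     "invalid_config")
  assert_fraction(censor_rate, "censor_rate", allow_one = FALSE)
  assert_fraction(decoy_rate, "decoy_rate")
  if (n_prognostic < 0 || n_prognostic > n_planted)
    stop_sponge("n_prognostic must be in [0, n_planted]", "invalid_config")
  structure(list(n_samples = as.integer(n_samples),
                 n_planted = as.integer(n_planted),
                 n_null_confounded = as.integer(n_null_confounded),
                 n_null_independent = as.integer(n_null_independent),
                 coupling_strength = coupling_strength, noise_sd = noise_sd,
                 hazard_ratio = hazard_ratio, censor_rate = censor_rate,
                 decoy_rate = decoy_rate,
                 n_prognostic = as.integer(n_prognostic),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# log2-scale baselines: miRNAs sit higher than lncRNAs, mRNAs in between;
# values only shift the RPKM scale, all statistics are location-invariant.
.BASE_LOG2 <- c(lncRNA = 4, miRNA = 6, mRNA = 5)

#' Simulate expression matrices with planted sponge structure
#'
#' @param config a [sim_config()].
#' @return list with `expr` (an [expr_matrix()] on the RPKM scale) and
#'   `truth` (a `ground_truth` object: a `triplets` data frame with columns
#'   `lncrna`, `mirna`, `mrna`, `class` in
#'   planted/confounded_null/independent_null, `prognostic` flag and the
#'   recorded `direct_coupling` of confounded nulls, plus the config).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_trip <- config$n_planted + config$n_null_confounded +
    config$n_null_independent
  cls <- rep(c("planted", "confounded_null", "independent_null"),
             c(config$n_planted, config$n_null_confounded,
               config$n_null_independent))
  ids <- list(lnc = sprintf("LNC%04d", seq_len(n_trip)),
              mir = sprintf("MIR%04d", seq_len(n_trip)),
              mrna = sprintf("MRNA%04d", seq_len(n_trip)))
  n <- config$n_samples
  b <- config$coupling_strength
  s <- config$noise_sd
  marg_sd <- sqrt(b^2 + s^2)  # matched marginal spread for independent nulls

  with_seed(derive_seed(config$seed, "expression"), {
    lnc <- mir <- mrna <- matrix(0, n_trip, n)
    for (i in seq_len(n_trip)) {
      if (cls[i] == "independent_null") {
        mir[i, ] <- .BASE_LOG2[["miRNA"]] + rnorm(n, sd = marg_sd)
        lnc[i, ] <- .BASE_LOG2[["lncRNA"]] + rnorm(n, sd = marg_sd)
        mrna[i, ] <- .BASE_LOG2[["mRNA"]] + rnorm(n, sd = marg_sd)
      } else {
        z0 <- rnorm(n)
        ex <- rnorm(n, sd = s)
        ey <- rnorm(n, sd = s)
        mir[i, ] <- .BASE_LOG2[["miRNA"]] + z0
        lnc[i, ] <- .BASE_LOG2[["lncRNA"]] - b * z0 + ex
        direct <- if (cls[i] == "confounded_null") b * ex else 0
        mrna[i, ] <- .BASE_LOG2[["mRNA"]] - b * z0 + direct + ey
      }
    }
    vals <- rbind(lnc, mir, mrna)
    rownames(vals) <- c(ids$lnc, ids$mir, ids$mrna)
    colnames(vals) <- sprintf("P%04d", seq_len(n))
    expr <- expr_matrix(2^vals,
                        rep(c("lncRNA", "miRNA", "mRNA"), each = n_trip),
                        subtype = "synthetic", scale = "rpkm")
    truth <- structure(list(
      triplets = data.frame(
        lncrna = ids$lnc, mirna = ids$mir, mrna = ids$mrna, class = cls,
        prognostic = cls == "planted" &
          seq_len(n_trip) <= config$n_prognostic,
        direct_coupling = ifelse(cls == "confounded_null", b, 0),
        stringsAsFactors = FALSE),
      config = config), class = "ground_truth")
    list(expr = expr, truth = truth)
  })
}

#' Simulate patient survival with a planted triplet-pattern effect
#'
#' Event times are exponential.  For each prognostic planted triplet, a
#' patient is *concordant* if their expression matches either sponge pattern
#' at the per-RNA medians — up-down-up (lncRNA high, miRNA low, mRNA high) or
#' down-up-down.  Concordant patients receive hazard multiplied by
#' `hazard_ratio`, discordant patients by `1/hazard_ratio`.  Because the
#' log-scale generator is sign-symmetric around the medians, every
#' *single*-RNA split has exactly null prognostic value while the triplet
#' pattern carries the whole effect — the situation the pattern-based
#' survival screen is designed to detect.  Censoring is independent: each
#' patient is censored with probability `censor_rate` at a uniform fraction
#' of their event time.
#'
#' @param expr,truth output of [simulate_expression()].
#' @param config the same [sim_config()].
#' @return data.frame with columns `patient`, `time`, `event`.
#' @export
simulate_survival <- function(expr, truth, config) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(truth, "ground_truth"))
  n <- ncol(expr$values)
  base_rate <- log(2) / 1000  # median survival 1000 days at multiplier 1
  mult <- rep(1, n)
  prog <- truth$triplets[truth$triplets$prognostic, , drop = FALSE]
  for (k in seq_len(nrow(prog))) {
    v <- expr$values
    up <- function(id) v[id, ] > median(v[id, ])
    updownup <- up(prog$lncrna[k]) & !up(prog$mirna[k]) & up(prog$mrna[k])
    downupdown <- !up(prog$lncrna[k]) & up(prog$mirna[k]) & !up(prog$mrna[k])
    concordant <- updownup | downupdown
    mult <- mult * ifelse(concordant, config$hazard_ratio,
                          1 / config$hazard_ratio)
  }
  with_seed(derive_seed(config$seed, "survival"), {
    time <- rexp(n, rate = base_rate * mult)
    censored <- runif(n) < config$censor_rate
    time[censored] <- time[censored] * runif(sum(censored))
    data.frame(patient = colnames(expr$values),
               time = time, event = as.integer(!censored),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a miRNA-target database with planted support and decoys
#'
#' Every planted triplet contributes its (miRNA, lncRNA) and (miRNA, mRNA)
#' pair.  Decoys are drawn from cross-triplet (miRNA, target) pairs — which
#' never coincide with planted pairs — each included independently with
#' probability `decoy_rate`.  Sources are fake database names; evidence class
#' is `P` (predicted) or `E` (experimental).
#'
#' @param truth a `ground_truth` object.
#' @param decoy_rate per-pair decoy inclusion probability.
#' @param seed RNG seed.
#' @return data.frame with columns `mirna`, `target`, `target_class`,
#'   `source`, `evidence`.
#' @export
simulate_target_db <- function(truth, decoy_rate = 0.1, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  assert_fraction(decoy_rate, "decoy_rate")
  tri <- truth$triplets
  planted <- tri[tri$class == "planted", , drop = FALSE]
  if (nrow(planted) == 0)
    stop_sponge("ground truth has no planted triplets", "invalid_input")
  db <- rbind(
    data.frame(mirna = planted$mirna, target = planted$lncrna,
               target_class = "lncRNA", stringsAsFactors = FALSE),
    data.frame(mirna = planted$mirna, target = planted$mrna,
               target_class = "mRNA", stringsAsFactors = FALSE))
  with_seed(derive_seed(seed, "target_db"), {
    db$source <- sample(c("synthTargetA", "synthTargetB"), nrow(db),
                        replace = TRUE)
    db$evidence <- sample(c("P", "E"), nrow(db), replace = TRUE)
    if (decoy_rate > 0) {
      n_tri <- nrow(tri)
      cand_lnc <- expand.grid(mi = seq_len(n_tri), tg = seq_len(n_tri))
      cand_lnc <- cand_lnc[cand_lnc$mi != cand_lnc$tg, ]
      keep_l <- runif(nrow(cand_lnc)) < decoy_rate
      keep_g <- runif(nrow(cand_lnc)) < decoy_rate
      decoys <- rbind(
        data.frame(mirna = tri$mirna[cand_lnc$mi[keep_l]],
                   target = tri$lncrna[cand_lnc$tg[keep_l]],
                   target_class = rep("lncRNA", sum(keep_l)),
                   stringsAsFactors = FALSE),
        data.frame(mirna = tri$mirna[cand_lnc$mi[keep_g]],
                   target = tri$mrna[cand_lnc$tg[keep_g]],
                   target_class = rep("mRNA", sum(keep_g)),
                   stringsAsFactors = FALSE))
      if (nrow(decoys)) {
        decoys$source <- sample(c("synthDecoyA", "synthDecoyB"),
                                nrow(decoys), replace = TRUE)
        decoys$evidence <- "P"
        db <- rbind(db, decoys)
      }
    }
    rownames(db) <- NULL
    db
  })
}

#' Simulate genomic coordinates with a controlled proximal fraction
#'
#' A chosen fraction of the planted triplets have their lncRNA and mRNA
#' placed on the same chromosome with an inter-gene gap drawn uniformly in
#' `[0, 100000]` bp; all other RNAs (including every member of non-proximal
#' and null triplets) are placed on chromosomes distinct within their
#' triplet, so only the deliberately placed pairs can ever be proximal.
#'
#' @param truth a `ground_truth` object.
#' @param proximal_fraction fraction of planted triplets placed proximally.
#' @param seed RNG seed.
#' @return a `sponge_annotation` list: `locations` (data.frame `rna`,
#'   `chromosome`, `start`, `end`, `strand`) and `proximal_triplets`
#'   (planted triplets with their placement flag).
#' @export
simulate_annotation <- function(truth, proximal_fraction = 0.5, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  assert_fraction(proximal_fraction, "proximal_fraction")
  tri <- truth$triplets
  planted_idx <- which(tri$class == "planted")
  n_prox <- round(proximal_fraction * length(planted_idx))
  chroms <- paste0("chr", 1:22)
  with_seed(derive_seed(seed, "annotation"), {
    prox_idx <- if (n_prox > 0) sort(sample(planted_idx, n_prox)) else
      integer(0)
    loc <- list()
    add <- function(rna, chrom, start, len) {
      data.frame(rna = rna, chromosome = chrom,
                 start = start, end = start + len - 1,
                 strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(tri))) {
      if (i %in% prox_idx) {
        chr <- sample(chroms, 2)  # [1] shared by lncRNA+mRNA, [2] miRNA
        s <- sample.int(5e7, 1)
        gap <- sample.int(100001L, 1) - 1L  # inclusive 100 kb boundary
        loc[[length(loc) + 1]] <- add(tri$lncrna[i], chr[1], s, 2000)
        loc[[length(loc) + 1]] <- add(tri$mrna[i], chr[1],
                                      s + 2000 + gap, 3000)
        loc[[length(loc) + 1]] <- add(tri$mirna[i], chr[2],
                                      sample.int(5e7, 1), 100)
      } else {
        chr <- sample(chroms, 3)
        loc[[length(loc) + 1]] <- add(tri$lncrna[i], chr[1],
                                      sample.int(5e7, 1), 2000)
        loc[[length(loc) + 1]] <- add(tri$mrna[i], chr[2],
                                      sample.int(5e7, 1), 3000)
        loc[[length(loc) + 1]] <- add(tri$mirna[i], chr[3],
                                      sample.int(5e7, 1), 100)
      }
    }
    planted <- tri[planted_idx, c("lncrna", "mirna", "mrna")]
    planted$proximal <- planted_idx %in% prox_idx
    structure(list(locations = do.call(rbind, loc),
                   proximal_triplets = planted),
              class = "sponge_annotation")
  })
}

#' Write ground truth as JSON
#'
#' @param truth a `ground_truth` object.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(triplets = truth$triplets, config = unclass(truth$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write simulated locations as a 9-column GTF
#'
#' One `gene` feature per RNA, 1-based inclusive coordinates, `gene_id`
#' attribute.
#'
#' @param annotation a `sponge_annotation` or its `locations` data.frame.
#' @param path output path.
#' @export
write_gtf <- function(annotation, path) {
  loc <- if (inherits(annotation, "sponge_annotation"))
    annotation$locations else annotation
  lines <- sprintf(
    "%s\tspongescout\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    loc$chromosome, loc$start, loc$end, loc$strand, loc$rna)
  writeLines(lines, path)
  invisible(path)
}
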