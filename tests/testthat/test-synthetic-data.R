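test_that("config validation rejects degenerate worlds", {
  expect_error(sim_config(n_samples = 5), class = "invalid_config")
  expect_error(sim_config(noise_sd = 0), class = "invalid_config")
  expect_error(sim_config(censor_rate = 1), class = "invalid_config")
  expect_error(sim_config(hazard_ratio = -1), class = "invalid_config")
  expect_error(sim_config(n_planted = 0), class = "invalid_config")
})

test_that("identical config gives bit-identical outputs, including files", {
  s1 <- small_sim(seed = 11)
  s2 <- small_sim(seed = 11)
  expect_identical(s1$expr$values, s2$expr$values)
  expect_identical(s1$truth$triplets, s2$truth$triplets)
  f1 <- tempfile(); f2 <- tempfile()
  write_expression_tsv(s1$expr, f1)
  write_expression_tsv(s2$expr, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- small_sim(seed = 12)
  expect_false(identical(s1$expr$values, s3$expr$values))
})

test_that("planted triplets carry the sponge correlation signature", {
  sim <- small_sim(seed = 1, n_samples = 200, n_planted = 10)
  v <- log2(sim$expr$values)
  tri <- sim$truth$triplets
  for (i in which(tri$class == "planted")) {
    x <- v[tri$lncrna[i], ]; y <- v[tri$mrna[i], ]; z <- v[tri$mirna[i], ]
    expect_gt(cor(x, y, method = "spearman"), 0.5)
    expect_lt(cor(x, z, method = "spearman"), 0)
    expect_lt(cor(y, z, method = "spearman"), 0)
  }
})

test_that("planted triplets are conditionally independent, confounded are not", {
  # partial Spearman averaged over replicates: ~0 for planted, away from 0
  # for confounded nulls
  pc_planted <- pc_conf <- numeric(20)
  for (r in 1:20) {
    sim <- small_sim(seed = 100 + r, n_samples = 1000, n_planted = 1,
                     n_conf = 1, n_indep = 1)
    v <- log2(sim$expr$values)
    tri <- sim$truth$triplets
    pc <- function(i) partial_spearman_oracle(v[tri$lncrna[i], ],
                                              v[tri$mrna[i], ],
                                              v[tri$mirna[i], ])
    pc_planted[r] <- pc(which(tri$class == "planted"))
    pc_conf[r] <- pc(which(tri$class == "confounded_null"))
  }
  expect_lt(abs(mean(pc_planted)), 0.05)
  expect_gt(mean(pc_conf), 0.5)
})

test_that("zero coupling makes planted triplets independent nulls", {
  sim <- small_sim(seed = 3, n_samples = 500, coupling_strength = 0,
                   noise_sd = 1)
  v <- log2(sim$expr$values)
  tri <- sim$truth$triplets
  rho <- sapply(which(tri$class == "planted"), function(i)
    cor(v[tri$lncrna[i], ], v[tri$mrna[i], ], method = "spearman"))
  expect_lt(max(abs(rho)), 0.15)
})

test_that("survival generator honours censor_rate and hazard_ratio contracts", {
  sim <- small_sim(seed = 5, n_samples = 100)
  cfg0 <- sim$cfg; cfg0$censor_rate <- 0
  surv0 <- simulate_survival(sim$expr, sim$truth, cfg0)
  expect_true(all(surv0$event == 1))
  expect_identical(surv0$patient, colnames(sim$expr$values))

  # hazard_ratio = 1: pattern group and complement share one survival law;
  # log-rank on the true median-pattern split rejects at ~nominal rate
  rej <- numeric(40)
  for (r in 1:40) {
    cfg <- sim_config(n_samples = 120, n_planted = 1, n_null_confounded = 1,
                      n_null_independent = 1, coupling_strength = 0,
                      noise_sd = 1, hazard_ratio = 1, seed = 400 + r)
    s <- simulate_expression(cfg)
    sv <- simulate_survival(s$expr, s$truth, cfg)
    tri <- s$truth$triplets[1, ]
    v <- s$expr$values
    up <- function(id) v[id, ] > median(v[id, ])
    pat <- up(tri$lncrna) & !up(tri$mirna) & up(tri$mrna)
    if (sum(pat) < 3) next
    rej[r] <- logrank(sv[pat, ], sv[!pat, ])$p < 0.05
  }
  expect_lt(mean(rej), 0.15)
})

test_that("planted survival effect is detectable on the true pattern split", {
  # hazard_ratio = 3, n = 200, censoring 20%: power of the log-rank on the
  # true up-down-up split should be >= 0.8 over replicates
  rej <- numeric(25)
  for (r in 1:25) {
    cfg <- sim_config(n_samples = 200, n_planted = 1, n_null_confounded = 1,
                      n_null_independent = 1, coupling_strength = 0,
                      noise_sd = 1, hazard_ratio = 3, censor_rate = 0.2,
                      seed = 500 + r)
    s <- simulate_expression(cfg)
    sv <- simulate_survival(s$expr, s$truth, cfg)
    tri <- s$truth$triplets[1, ]
    v <- s$expr$values
    up <- function(id) v[id, ] > median(v[id, ])
    pat <- up(tri$lncrna) & !up(tri$mirna) & up(tri$mrna)
    rej[r] <- logrank(sv[pat, ], sv[!pat, ])$p < 0.05
  }
  expect_gte(mean(rej), 0.8)
})

test_that("target database covers planted pairs exactly at decoy_rate 0", {
  sim <- small_sim(seed = 9)
  db <- simulate_target_db(sim$truth, decoy_rate = 0, seed = 1)
  planted <- sim$truth$triplets[sim$truth$triplets$class == "planted", ]
  expect_setequal(paste(db$mirna, db$target),
                  c(paste(planted$mirna, planted$lncrna),
                    paste(planted$mirna, planted$mrna)))
  # both sides present for a specific planted triplet
  expect_true(paste(planted$mirna[1], planted$lncrna[1]) %in%
                paste(db$mirna, db$target))
  expect_true(paste(planted$mirna[1], planted$mrna[1]) %in%
                paste(db$mirna, db$target))
})

test_that("decoy count concentrates at decoy_rate x candidate pairs", {
  sim <- small_sim(seed = 13, n_planted = 2, n_conf = 2, n_indep = 2)
  n_tri <- nrow(sim$truth$triplets)
  n_cand <- 2 * n_tri * (n_tri - 1)  # lncRNA-side + mRNA-side cross pairs
  counts <- sapply(1:40, function(s) {
    db <- simulate_target_db(sim$truth, decoy_rate = 0.1, seed = s)
    sum(grepl("Decoy", db$source))
  })
  expect_equal(mean(counts), 0.1 * n_cand, tolerance = 0.15)
  # decoys never coincide with planted pairs
  db <- simulate_target_db(sim$truth, decoy_rate = 0.3, seed = 2)
  planted <- sim$truth$triplets[sim$truth$triplets$class == "planted", ]
  planted_keys <- c(paste(planted$mirna, planted$lncrna),
                    paste(planted$mirna, planted$mrna))
  decoy_keys <- paste(db$mirna, db$target)[grepl("Decoy", db$source)]
  expect_length(intersect(decoy_keys, planted_keys), 0)
})

test_that("annotation places the requested fraction proximally", {
  sim <- small_sim(seed = 21, n_planted = 20)
  for (frac in c(0, 0.5, 1)) {
    ann <- simulate_annotation(sim$truth, proximal_fraction = frac, seed = 5)
    expect_equal(sum(ann$proximal_triplets$proximal), round(frac * 20))
    scan <- proximal_triplets(ann$proximal_triplets, ann)
    expect_equal(scan$n_proximal_pairs > 0, ann$proximal_triplets$proximal)
  }
  # every RNA in the truth has one location
  ann <- simulate_annotation(sim$truth, 0.5, seed = 5)
  tri <- sim$truth$triplets
  expect_setequal(ann$locations$rna,
                  c(tri$lncrna, tri$mirna, tri$mrna))
  expect_true(all(ann$locations$start <= ann$locations$end))
})

test_that("truth and matrices agree; planted and null ids are disjoint", {
  sim <- small_sim(seed = 2)
  tri <- sim$truth$triplets
  ids <- c(tri$lncrna, tri$mirna, tri$mrna)
  expect_true(all(ids %in% rownames(sim$expr$values)))
  planted <- tri[tri$class == "planted", ]
  nulls <- tri[tri$class != "planted", ]
  expect_length(intersect(
    paste(planted$lncrna, planted$mirna, planted$mrna),
    paste(nulls$lncrna, nulls$mirna, nulls$mrna)), 0)
})
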