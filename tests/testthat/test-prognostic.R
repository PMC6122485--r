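test_that("candidate cutoffs follow the interpolation convention", {
  cand <- candidate_cutoffs(1:100)
  get <- function(lab) cand$cutoff[cand$label == lab]
  expect_equal(get("P10"), 10.9)
  expect_equal(get("median"), 50.5)
  expect_equal(get("Q3"), 75.25)
  expect_equal(get("mean"), 50.5)
  expect_equal(nrow(cand), 6)  # duplicates retained with distinct labels
  expect_error(candidate_cutoffs(rep(2, 30)), class = "degenerate_cutoff")
  expect_error(candidate_cutoffs(1:10), class = "invalid_input")
})

test_that("logrank matches the hand-tabulated fixture", {
  # groups (2,4,6) vs (1,3,5), all events: O-E and variance tabulated by
  # hand over the six distinct event times give chisq = 529/1091
  gA <- data.frame(time = c(2, 4, 6), event = 1)
  gB <- data.frame(time = c(1, 3, 5), event = 1)
  lr <- logrank(gA, gB)
  expect_equal(lr$statistic, 529 / 1091, tolerance = 1e-6)
  expect_equal(lr$p, pchisq(529 / 1091, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  # identical groups: statistic 0, p 1
  lr0 <- logrank(gA, gA)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)
  # all-censored input signals p = 1
  cens <- data.frame(time = c(3, 9), event = 0)
  expect_equal(logrank(cens, cens)$p, 1)
  expect_error(logrank(gA, gA[0, ]), class = "invalid_input")
})

test_that("logrank agrees with a permutation reference", {
  set.seed(71)
  n <- 40
  grp <- rep(c(TRUE, FALSE), each = n / 2)
  time <- rexp(n, ifelse(grp, 1 / 800, 1 / 1400))
  event <- as.integer(runif(n) > 0.2)
  df <- data.frame(time = time, event = event)
  obs <- logrank(df[grp, ], df[!grp, ])
  B <- 2000
  perm_stats <- replicate(B, {
    g <- sample(grp)
    logrank(df[g, ], df[!g, ])$statistic
  })
  p_perm <- (1 + sum(perm_stats >= obs$statistic)) / (1 + B)
  expect_lt(abs(obs$p - p_perm), 0.04)
})

test_that("select_cutoff honours the group-size rule and minimizes p", {
  set.seed(81)
  vals <- rnorm(50)
  surv <- null_survival(50, seed = 82)
  got <- select_cutoff(vals, surv)
  # independent recount: valid splits and their p-values
  cand <- candidate_cutoffs(vals)
  ps <- sapply(seq_len(nrow(cand)), function(k) {
    up <- vals > cand$cutoff[k]
    if (sum(up) <= 10 || sum(!up) <= 10) return(NA_real_)
    logrank(surv[up, ], surv[!up, ])$p
  })
  expect_true(is.na(ps[cand$label == "P90"]))  # only 5 above P90 at n=50
  expect_true(is.na(ps[cand$label == "P10"]))
  expect_equal(got$p, min(ps, na.rm = TRUE))
  expect_equal(got$label, cand$label[which.min(ps)])
  # no valid split at all
  tiny <- null_survival(21, seed = 83)
  expect_null(select_cutoff(rnorm(21), tiny))
})

test_that("pattern groups match manual membership evaluation", {
  lnc <- c(5, 1, 5, 5, 1, 5)
  mir <- c(2, 9, 2, 9, 2, 2)
  mrna <- c(7, 3, 3, 7, 7, 7)
  up <- pattern_groups(lnc, mir, mrna, 3, 5, 5, "up-down-up")
  expect_identical(up, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  down <- pattern_groups(lnc, mir, mrna, 3, 5, 5, "down-up-down")
  expect_identical(down, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(any(up & down))  # contradictory inequalities
  # ties sit on the down side: a fully tied patient fits neither pattern
  # (miRNA tie counts as down), and flipping the miRNA above its cutoff
  # completes down-up-down
  expect_identical(pattern_groups(3, 5, 5, 3, 5, 5, "up-down-up"), FALSE)
  expect_identical(pattern_groups(3, 5, 5, 3, 5, 5, "down-up-down"), FALSE)
  expect_identical(pattern_groups(3, 6, 5, 3, 5, 5, "down-up-down"), TRUE)
})

test_that("evaluate_triplet reports consistent statistics and verdicts", {
  cfg <- sim_config(n_samples = 200, n_planted = 2, n_null_confounded = 1,
                    n_null_independent = 1, coupling_strength = 0,
                    noise_sd = 1, hazard_ratio = 3, censor_rate = 0.2,
                    n_prognostic = 1, seed = 91)
  sim <- simulate_expression(cfg)
  surv <- simulate_survival(sim$expr, sim$truth, cfg)
  pre <- log2_transform(missingness_filter(sim$expr))
  res <- prognostic_screen(sim$truth$triplets, pre, surv)
  expect_equal(nrow(res), 4)
  ok <- res[res$verdict != "not_evaluable", ]
  # f-score identity on every evaluated triplet
  expect_equal(ok$f_score,
               -log10(ok$p_xyz / pmin(ok$p_x, ok$p_y, ok$p_z)),
               tolerance = 1e-12)
  # group-size rule
  expect_true(all(ok$n_pattern > 10 & ok$n_rest > 10))
  # verdict logic: prognostic iff p_xyz < .05 and all singles >= .05,
  # which forces f_score > 0
  prog <- ok[ok$verdict == "prognostic", ]
  if (nrow(prog)) {
    expect_true(all(prog$p_xyz < 0.05))
    expect_true(all(pmin(prog$p_x, prog$p_y, prog$p_z) >= 0.05))
    expect_true(all(prog$f_score > 0))
  }
  # ranking is by decreasing f-score
  expect_false(is.unsorted(rev(ok$f_score)))
})

test_that("a planted pattern effect is detected at the true cutoffs", {
  # bypass cutoff selection: at the generating medians the pattern split
  # separates survival while single median splits do not
  hits_pattern <- hits_single <- 0
  for (r in 1:15) {
    cfg <- sim_config(n_samples = 200, n_planted = 1, n_null_confounded = 1,
                      n_null_independent = 1, coupling_strength = 0,
                      noise_sd = 1, hazard_ratio = 3, censor_rate = 0.2,
                      seed = 900 + r)
    sim <- simulate_expression(cfg)
    surv <- simulate_survival(sim$expr, sim$truth, cfg)
    tri <- sim$truth$triplets[1, ]
    v <- sim$expr$values
    up <- function(id) v[id, ] > median(v[id, ])
    pat <- up(tri$lncrna) & !up(tri$mirna) & up(tri$mrna)
    hits_pattern <- hits_pattern +
      (logrank(surv[pat, ], surv[!pat, ])$p < 0.05)
    sl <- up(tri$lncrna)
    hits_single <- hits_single + (logrank(surv[sl, ], surv[!sl, ])$p < 0.05)
  }
  expect_gte(hits_pattern / 15, 0.8)
  expect_lte(hits_single / 15, 0.2)
})
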