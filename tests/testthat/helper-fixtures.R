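# Shared fixture builders; everything is generated in code at test time.

small_sim <- function(seed = 7, n_samples = 120, n_planted = 4,
                      n_conf = 3, n_indep = 3, ...) {
  cfg <- sim_config(n_samples = n_samples, n_planted = n_planted,
                    n_null_confounded = n_conf, n_null_independent = n_indep,
                    seed = seed, ...)
  sim <- simulate_expression(cfg)
  list(cfg = cfg, expr = sim$expr, truth = sim$truth)
}

# Log2 expression matrix straight from the simulator (skipping the MAD
# filter, which planted rows always pass anyway at the default config).
small_log2 <- function(sim) log2_transform(missingness_filter(sim$expr))

# Independent oracle for the partial Spearman correlation: Pearson
# correlation of the residuals of rank-regressions on the conditioning
# variable's ranks.
partial_spearman_oracle <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  cor(resid(lm(rx ~ rz)), resid(lm(ry ~ rz)))
}

# Exponential survival with no link to anything (a null world).
null_survival <- function(n, censor = 0.2, seed = 1) {
  set.seed(seed)
  data.frame(patient = sprintf("P%04d", seq_len(n)),
             time = rexp(n, log(2) / 1000),
             event = as.integer(runif(n) >= censor))
}

fast_kci <- function(seed = 1, n_null_draws = 500) {
  kernel_config(n_null_draws = n_null_draws, seed = seed)
}
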