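#' Configuration for the kernel independence tests
#'
#' @param sigma_rule kernel-width heuristic; only `"median"` (median pairwise
#'   distance of the standardized input) is implemented.  It makes the tests
#'   invariant to positive rescaling of the inputs.
#' @param n_null_draws Monte-Carlo draws from the eigenvalue null
#'   (>= 100; default 1000).
#' @param eig_threshold relative eigenvalue truncation: eigenvalues below
#'   `eig_threshold * max(eigenvalue)` are dropped from the null.
#' @param ridge_epsilon ridge regularization of the kernel-regression
#'   residual operator used for conditioning.
#' @param alpha significance level (the pipeline uses 0.01).
#' @param null_mode `"montecarlo"` (reference) or `"gamma"` (moment-matched
#'   gamma approximation of the null, faster).
#' @param seed RNG seed for the null draws.
#' @return a `kernel_config` list.
#' @export
kernel_config <- function(sigma_rule = "median", n_null_draws = 1000,
                          eig_threshold = 1e-5, ridge_epsilon = 1e-3,
                          alpha = 0.01, null_mode = c("montecarlo", "gamma"),
                          seed = 1) {
  if (n_null_draws < 100)
    stop_sponge("n_null_draws must be >= 100", "invalid_config")
  if (eig_threshold <= 0 || eig_threshold >= 1)
    stop_sponge("eig_threshold must be in (0, 1)", "invalid_config")
  if (ridge_epsilon <= 0)
    stop_sponge("ridge_epsilon must be > 0", "invalid_config")
  structure(list(sigma_rule = match.arg(sigma_rule, "median"),
                 n_null_draws = as.integer(n_null_draws),
                 eig_threshold = eig_threshold,
                 ridge_epsilon = ridge_epsilon, alpha = alpha,
                 null_mode = match.arg(null_mode), seed = as.integer(seed)),
            class = "kernel_config")
}

#' Gaussian (RBF) kernel matrix
#'
#' `K[i, j] = exp(-||x_i - x_j||^2 / (2 sigma^2))`.
#'
#' @param x numeric vector, or matrix with one sample per row.
#' @param sigma kernel width (> 0).
#' @return the n x n kernel matrix (symmetric, unit diagonal).
#' @export
gaussian_kernel <- function(x, sigma) {
  if (sigma <= 0) stop_sponge("sigma must be > 0", "invalid_input")
  x <- as.matrix(x)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Double-center a kernel matrix
#'
#' `HKH` with `H = I - (1/n) 11'`: row and column sums of the result are 0.
#'
#' @param K square symmetric kernel matrix.
#' @return the centered kernel matrix.
#' @export
centralize <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop_sponge("K must be a square matrix", "invalid_input")
  rm_ <- rowMeans(K)
  K - outer(rm_, rep(1, ncol(K))) - outer(rep(1, nrow(K)), colMeans(K)) +
    mean(K)
}

# Median-heuristic kernel width on the standardized input (n x d matrix).
median_sigma <- function(x) {
  x <- as.matrix(x)
  d <- as.vector(dist(x))
  s <- median(d[d > 0])
  if (!is.finite(s) || s <= 0) 1 else s
}

standardize <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2L, sd)
  if (any(s == 0)) return(NULL)  # caller handles the degenerate case
  scale(x, center = TRUE, scale = s)
}

trunc_eigs <- function(lambda, rel) {
  lambda <- lambda[lambda > rel * max(lambda, 0) & lambda > 0]
  lambda
}

degenerate_result <- function(cfg) {
  warning("constant input: kernel matrix is degenerate, returning p = 1",
          call. = FALSE)
  structure(list(statistic = 0, p_value = 1, n_eigs_used = 0L,
                 null_draws_used = 0L), class = "kci_result")
}

#' @export
print.kci_result <- function(x, ...) {
  cat(sprintf("<kci_result> statistic = %.4g, p = %.4g (%d eigenvalues, %d null draws)\n",
              x$statistic, x$p_value, x$n_eigs_used, x$null_draws_used))
  invisible(x)
}

# Empirical p with the +1 correction (never exactly 0).
empirical_p <- function(stat, null_draws) {
  (1 + sum(null_draws >= stat)) / (1 + length(null_draws))
}

gamma_p <- function(stat, mean_null, var_null) {
  shape <- mean_null^2 / var_null
  rate <- mean_null / var_null
  pgamma(stat, shape = shape, rate = rate, lower.tail = FALSE)
}

#' Kernel unconditional independence test
#'
#' Tests whether two samples are independent with the trace statistic
#' `T = (1/n) Tr(Kx~ Ky~)` of the centered Gaussian kernel matrices.  Under
#' independence the statistic is asymptotically a doubly-infinite weighted
#' sum of chi-squares with weights given by the products of the kernel
#' eigenvalues; the null is simulated by drawing
#' `(1/n^2) sum_{i,j} lambda_x,i lambda_y,j z_ij^2` with `z_ij^2 ~ chisq(1)`,
#' eigenvalues truncated at `eig_threshold` relative to the largest.
#'
#' @param x,y numeric vectors of equal length (n >= 20 recommended).
#' @param cfg a [kernel_config()].
#' @return a `kci_result`: `statistic`, `p_value`, `n_eigs_used`,
#'   `null_draws_used`.
#' @export
kci_u <- function(x, y, cfg = kernel_config()) {
  n <- length(x)
  stopifnot(length(y) == n)
  xs <- standardize(x); ys <- standardize(y)
  if (is.null(xs) || is.null(ys)) return(degenerate_result(cfg))
  Kx <- centralize(gaussian_kernel(xs, median_sigma(xs)))
  Ky <- centralize(gaussian_kernel(ys, median_sigma(ys)))
  stat <- sum(Kx * Ky) / n
  lx <- trunc_eigs(eigen(Kx, symmetric = TRUE, only.values = TRUE)$values,
                   cfg$eig_threshold)
  ly <- trunc_eigs(eigen(Ky, symmetric = TRUE, only.values = TRUE)$values,
                   cfg$eig_threshold)
  w <- as.vector(outer(lx, ly)) / n^2
  if (cfg$null_mode == "gamma") {
    p <- gamma_p(stat, sum(w), 2 * sum(w^2))
    null_used <- 0L
  } else {
    null <- with_seed(derive_seed(cfg$seed, "kci_u"), {
      zz <- matrix(rchisq(length(w) * cfg$n_null_draws, df = 1),
                   nrow = length(w))
      as.vector(crossprod(zz, w))
    })
    p <- empirical_p(stat, null)
    null_used <- cfg$n_null_draws
  }
  structure(list(statistic = stat, p_value = p,
                 n_eigs_used = length(w), null_draws_used = null_used),
            class = "kci_result")
}

# Kernel-ridge residual operator Rz = eps * (Kz~ + eps I)^{-1} and the
# conditioned (residualized) kernel Rz K~ Rz.
residual_operator <- function(Kz_c, eps) {
  n <- nrow(Kz_c)
  eps * solve(Kz_c + diag(eps, n))
}

#' Kernel conditional independence test
#'
#' Tests X independent of Y given Z.  The X side is augmented with the
#' conditioning variable (`X" = (X, Z)`, standardized jointly); kernel
#' matrices are residualized with the kernel-ridge operator
#' `Rz = eps (Kz~ + eps I)^{-1}` so that
#' `K~_{X"|Z} = Rz K~_{X"} Rz` and `K~_{Y|Z} = Rz K~_Y Rz`.  The statistic
#' is `(1/n) Tr(K~_{X"|Z} K~_{Y|Z})`.  The null is simulated from the
#' spectral-product construction: with eigenvectors/values of the two
#' residualized kernels, the feature matrix `W` whose columns are the
#' elementwise products of scaled eigenvectors yields weights
#' `lambda*_k = eig(W'W)`, and the null draws are
#' `(1/n) sum_k lambda*_k z_k^2`.
#'
#' @param x,y,z numeric vectors of equal length.
#' @param cfg a [kernel_config()].
#' @return a `kci_result`.
#' @export
kci_c <- function(x, y, z, cfg = kernel_config()) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  xs <- standardize(x); ys <- standardize(y); zs <- standardize(z)
  if (is.null(xs) || is.null(ys) || is.null(zs))
    return(degenerate_result(cfg))
  xz <- cbind(xs, zs)
  Kxz <- centralize(gaussian_kernel(xz, median_sigma(xz)))
  Ky <- centralize(gaussian_kernel(ys, median_sigma(ys)))
  Kz <- centralize(gaussian_kernel(zs, median_sigma(zs)))
  Rz <- residual_operator(Kz, cfg$ridge_epsilon)
  Kx_res <- Rz %*% Kxz %*% Rz
  Ky_res <- Rz %*% Ky %*% Rz
  Kx_res <- (Kx_res + t(Kx_res)) / 2
  Ky_res <- (Ky_res + t(Ky_res)) / 2
  stat <- sum(Kx_res * Ky_res) / n

  ex <- eigen(Kx_res, symmetric = TRUE)
  ey <- eigen(Ky_res, symmetric = TRUE)
  kx <- sum(ex$values > cfg$eig_threshold * max(ex$values, 0) &
              ex$values > 0)
  ky <- sum(ey$values > cfg$eig_threshold * max(ey$values, 0) &
              ey$values > 0)
  kx <- max(kx, 1L); ky <- max(ky, 1L)
  phix <- ex$vectors[, seq_len(kx), drop = FALSE] %*%
    diag(sqrt(ex$values[seq_len(kx)]), kx)
  phiy <- ey$vectors[, seq_len(ky), drop = FALSE] %*%
    diag(sqrt(ey$values[seq_len(ky)]), ky)
  # W: n x (kx*ky), columns are elementwise eigenvector products
  W <- matrix(0, n, kx * ky)
  for (i in seq_len(kx)) {
    W[, ((i - 1) * ky + 1):(i * ky)] <- phix[, i] * phiy
  }
  prod_mat <- if (ncol(W) > n) tcrossprod(W) else crossprod(W)
  lambdas <- eigen(prod_mat, symmetric = TRUE, only.values = TRUE)$values
  lambdas <- trunc_eigs(lambdas, cfg$eig_threshold)
  if (cfg$null_mode == "gamma") {
    p <- gamma_p(stat, sum(lambdas) / n, 2 * sum(lambdas^2) / n^2)
    null_used <- 0L
  } else {
    null <- with_seed(derive_seed(cfg$seed, "kci_c"), {
      zz <- matrix(rchisq(length(lambdas) * cfg$n_null_draws, df = 1),
                   nrow = length(lambdas))
      as.vector(crossprod(zz, lambdas)) / n
    })
    p <- empirical_p(stat, null)
    null_used <- cfg$n_null_draws
  }
  structure(list(statistic = stat, p_value = p,
                 n_eigs_used = length(lambdas), null_draws_used = null_used),
            class = "kci_result")
}

#' Confirm screened candidates with kernel independence tests
#'
#' For every distinct lncRNA:mRNA pair among the screened candidates, the
#' unconditional test must *reject* independence at `cfg$alpha` (the pair is
#' genuinely dependent).  For each surviving triplet the conditional test
#' given the miRNA must *not* reject (the dependence is fully explained by
#' the miRNA).  Triplets meeting both conditions are the potential
#' lncRNA-mediated ceRNAs.
#'
#' Each test derives its own seed from `cfg$seed` and the RNA ids, so
#' results do not depend on processing order.
#'
#' @param candidates data.frame from [screen_candidates()]; only rows with
#'   `passes_threshold` are tested.
#' @param m the preprocessed [expr_matrix()] the candidates came from.
#' @param cfg a [kernel_config()].
#' @return the retained candidate rows, augmented with `kci_u_stat`,
#'   `kci_u_p`, `kci_c_stat`, `kci_c_p` and `decision`.  The full tested
#'   set (with decisions) is attached as attribute `"tested"`.
#' @export
confirm_triplets <- function(candidates, m, cfg = kernel_config()) {
  stopifnot(inherits(m, "expr_matrix"))
  cand <- candidates[candidates$passes_threshold, , drop = FALSE]
  if (nrow(cand) == 0) {
    out <- cbind(cand, kci_u_stat = numeric(0), kci_u_p = numeric(0),
                 kci_c_stat = numeric(0), kci_c_p = numeric(0),
                 decision = character(0))
    attr(out, "tested") <- out
    return(out)
  }
  v <- m$values
  pairs <- unique(cand[, c("lncrna", "mrna")])
  pair_res <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    pcfg <- cfg
    pcfg$seed <- derive_seed(cfg$seed, paste("u", pairs$lncrna[k],
                                             pairs$mrna[k]))
    r <- kci_u(v[pairs$lncrna[k], ], v[pairs$mrna[k], ], pcfg)
    pair_res[[k]] <- c(stat = r$statistic, p = r$p_value)
  }
  pr <- do.call(rbind, pair_res)
  key <- paste(pairs$lncrna, pairs$mrna)
  idx <- match(paste(cand$lncrna, cand$mrna), key)
  cand$kci_u_stat <- pr[idx, "stat"]
  cand$kci_u_p <- pr[idx, "p"]
  cand$kci_c_stat <- NA_real_
  cand$kci_c_p <- NA_real_
  cand$decision <- "dropped_pair_independent"
  dep <- cand$kci_u_p < cfg$alpha
  for (k in which(dep)) {
    tcfg <- cfg
    tcfg$seed <- derive_seed(cfg$seed, paste("c", cand$lncrna[k],
                                             cand$mirna[k], cand$mrna[k]))
    r <- kci_c(v[cand$lncrna[k], ], v[cand$mrna[k], ], v[cand$mirna[k], ],
               tcfg)
    cand$kci_c_stat[k] <- r$statistic
    cand$kci_c_p[k] <- r$p_value
    cand$decision[k] <- if (r$p_value >= cfg$alpha) "retained"
    else "dropped_conditionally_dependent"
  }
  out <- cand[cand$decision == "retained", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- cand
  out
}
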