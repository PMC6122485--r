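#' @importFrom stats cor median quantile rnorm rexp rchisq runif rbinom
#'   pchisq pt pgamma sd setNames dist
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a base seed and a string key
#'
#' Stochastic stages (kernel-test null draws, per-subtype simulations) must be
#' reproducible independently of processing order.  Each stage derives its own
#' seed from the run seed and a stable string key via a small polynomial hash,
#' so shuffling subtypes or triplets never changes any stage's stream.
#'
#' @param seed integer base seed.
#' @param key character scalar identifying the stage.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647  # 2^31 - 1, keeps every derived seed a valid 32-bit integer
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so library code never clobbers a user's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_sponge <- function(msg, class, ...) {
  stop(structured_condition(
    msg, c(class, "spongescout_error", "error", "condition"), ...))
}

structured_condition <- function(msg, class, call = sys.call(-1)) {
  structure(class = class, list(message = msg, call = call))
}

assert_fraction <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    stop_sponge(sprintf("`%s` must be a fraction in [0, %s)", name,
                        if (allow_one) "1]" else "1"), "invalid_config")
  }
  invisible(x)
}
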