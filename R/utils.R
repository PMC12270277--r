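#' @importFrom stats cor cov sd var rnorm runif setNames median coef lm anova
#' @importFrom stats aov pt pf cor.test t.test resid fitted quantile qnorm
#' @importFrom stats format.pval
#' @importFrom rlang .data
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-subject / per-stream seed derivation. Exact in double
# precision (operands stay far below 2^53) and always < 2^31.
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  ((seed %% 2147483647) * 1000003 + stream * 100003 + index) %% 2147483647
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_symgeo <- function(...) stop(..., call. = FALSE)

# Fisher z transform with clipping away from +/-1
fisher_z <- function(r, eps = 1e-7) atanh(clip(r, -1 + eps, 1 - eps))

# 95% CI for a Pearson correlation on the Fisher scale
fisher_ci <- function(r, n, level = 0.95) {
  z <- fisher_z(r)
  h <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - h, z + h))
}
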