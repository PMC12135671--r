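# Internal helpers shared across modules.

# Structured errors: every user-facing failure carries a class under "mr_error"
# so callers (and the pipeline) can branch on the failure kind.
mr_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mr_error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.  All stochastic operations in the package route through this.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Two-sided normal / t p-values from an estimate and its standard error.
two_sided_p <- function(est, se, df = NULL) {
  z <- abs(est / se)
  if (is.null(df)) 2 * stats::pnorm(-z) else 2 * stats::pt(-z, df = df)
}

crit_quantile <- function(conf_level = 0.95, df = NULL) {
  a <- 1 - (1 - conf_level) / 2
  if (is.null(df)) stats::qnorm(a) else stats::qt(a, df = df)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
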