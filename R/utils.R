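# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the caller's `.Random.seed` afterwards so that
#' generators are pure functions of their seed and never disturb the global
#' RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive n reproducible child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Trapezoidal integral of y over a uniform grid with spacing dt.
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1L] + y[n]) / 2)
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("rhinoflow_format_error",
                                             "error", "condition")))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop_format(what, " contains non-finite values")
  invisible(x)
}
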