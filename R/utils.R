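# Internal helpers shared across modules.

# Moment-based Fisher-Pearson skewness g1 = m3 / m2^(3/2).
# Zero-variance vectors have undefined skewness; reported as 0 so that
# degenerate degree distributions (e.g. tiny fixtures) summarise cleanly.
skewness_g1 <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so that seeded routines do not clobber the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
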