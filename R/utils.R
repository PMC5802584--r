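# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

stop_ <- function(...) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# inverse-CDF draw from a normal truncated below at `lower` (exact, vectorised)
rtruncnorm_lower <- function(n, mean, sd, lower) {
  p0 <- pnorm(lower, mean, sd)
  u <- runif(n, p0, 1)
  qnorm(u, mean, sd)
}
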