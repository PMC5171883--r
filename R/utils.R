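# internal helpers shared across modules

ld_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "linedrift_error")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# If seed is NULL the current RNG stream is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x > 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# symmetric matrix square root with negative eigenvalues clamped to zero,
# so exactly singular correlation structures (e.g. r_g = 1) are usable
mat_sqrt <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

# draw n multivariate-normal rows given a precomputed matrix square root
rmvn_sqrt <- function(n, sq) {
  k <- ncol(sq)
  matrix(rnorm(n * k), n, k) %*% sq
}
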