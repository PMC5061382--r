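# evaluate expr under set.seed(seed) without disturbing the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  if (sum(g) <= 0) g <- rep(1, n)
  g / sum(g)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
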