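# Non-negative matrix factorization by multiplicative updates (Frobenius
# objective). Seeded uniform initialization; stops when the relative change of
# the objective falls below `tol` or after `max_iter` iterations.
nmf_factorize <- function(x, d, seed, tol = 1e-4, max_iter = 500L) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("NMF requires a non-negative matrix")
  n <- nrow(x); m <- ncol(x)
  if (d < 1 || d > min(n, m)) {
    stop(sprintf("rank d = %d must lie in [1, %d]", d, min(n, m)))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  scale0 <- sqrt(max(mean(x), .Machine$double.eps) / d)
  w <- matrix(stats::runif(n * d, min = 0.1, max = 1), n, d) * scale0
  h <- matrix(stats::runif(d * m, min = 0.1, max = 1), d, m) * scale0

  eps <- 1e-12
  xnorm2 <- sum(x^2)
  obj_prev <- Inf
  iters <- max_iter
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, x) / (crossprod(w) %*% h + eps))
    w <- w * (x %*% t(h)) / (w %*% tcrossprod(h) + eps)
    obj <- sum((x - w %*% h)^2)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= tol * max(obj_prev, eps)) {
      iters <- it
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  rel_err <- sqrt(max(obj_prev, 0)) / sqrt(max(xnorm2, eps))
  list(w = w, h = h, iterations = iters, relative_error = rel_err)
}
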