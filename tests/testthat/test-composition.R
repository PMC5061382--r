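test_that("training-pair extraction applies both frequency filters", {
  # "moon walk" 25x, "moon rock" 3x, filler sentences
  sents <- c(replicate(25, list(c("the", "moon", "walk", "now"))),
             replicate(3, list(c("a", "moon", "rock", "here"))))
  co <- tokenized_corpus(sents)
  ts <- extract_training_pairs(co, "moon", min_pair_freq = 20,
                               min_pairs_per_modifier = 1)
  expect_equal(ts$pairs$head, "walk")
  expect_equal(ts$pairs$freq, 25L)

  # a modifier below the pairs-per-modifier floor is dropped entirely
  ts2 <- extract_training_pairs(co, "moon", min_pair_freq = 20,
                                min_pairs_per_modifier = 2)
  expect_equal(nrow(ts2$pairs), 0L)
  expect_true("moon" %in% ts2$dropped_modifiers)

  # item pairs are excluded from training
  ts3 <- extract_training_pairs(co, "moon",
                                item_pairs = data.frame(modifier = "moon",
                                                        head = "walk"),
                                min_pair_freq = 20,
                                min_pairs_per_modifier = 1)
  expect_equal(nrow(ts3$pairs), 0L)
  expect_equal(ts3$excluded_items$head, "walk")
})

test_that("training-pair extraction is invariant to sentence order", {
  set.seed(43)
  gen <- generate_corpus(corpus_config(vocab_size = 80, n_topics = 3,
                                       n_sentences = 600, n_modifiers = 3,
                                       n_heads = 12, compound_rate = 0.3,
                                       n_item_pairs = 4, seed = 7))
  co <- gen$corpus
  perm <- tokenized_corpus(sample(co$sentences))
  a <- extract_training_pairs(co, gen$ledger$modifiers,
                              min_pair_freq = 3, min_pairs_per_modifier = 2)
  b <- extract_training_pairs(perm, gen$ledger$modifiers,
                              min_pair_freq = 3, min_pairs_per_modifier = 2)
  expect_equal(as.data.frame(a$pairs), as.data.frame(b$pairs))
})

test_that("lexical function recovers the identity map", {
  set.seed(47)
  h <- matrix(runif(30, 0.1, 1), 10, 3)
  fit <- fit_lexical_function(h, h, lambda = 1e-9)
  expect_lt(max(abs(fit$matrix - cbind(diag(3), 0))), 1e-6)
  # identity function composes to h exactly
  sp <- semantic_space(matrix(c(1, 2, 4), 1, 3,
                              dimnames = list("walk", NULL)))
  mod <- composition_model("lexical_function",
                           list(moon = fit))
  expect_equal(compose_compound(mod, "moon", "walk", sp), c(1, 2, 4),
               tolerance = 1e-5)
})

test_that("lexical function solves the hand-worked 2x2 system", {
  # no intercept: heads e1, e2 map to columns of M
  h <- rbind(c(1, 0), c(0, 1))
  p <- rbind(c(2, 1), c(0, 3))
  fit <- fit_lexical_function(h, p, lambda = 0, intercept = FALSE)
  expect_equal(unname(fit$matrix), rbind(c(2, 0), c(1, 3)), tolerance = 1e-10)
})

test_that("planted lexical functions and full-additive maps are recovered", {
  set.seed(53)
  d <- 10
  mstar <- matrix(rnorm(d * (d + 1)), d, d + 1)
  h <- matrix(runif(5 * d * d), 5 * d, d)
  p <- t(mstar %*% t(cbind(h, 1)))
  fit <- fit_lexical_function(h, p, lambda = 1e-8)
  expect_lt(norm(fit$matrix - mstar, "F") / norm(mstar, "F"), 1e-4)

  astar <- matrix(rnorm(d * d), d, d)
  bstar <- matrix(rnorm(d * d), d, d)
  m <- matrix(runif(10 * d * d), 10 * d, d)
  h2 <- matrix(runif(10 * d * d), 10 * d, d)
  p2 <- t(astar %*% t(m) + bstar %*% t(h2))
  fa <- fit_full_additive(m, h2, p2, lambda = 1e-8)
  err <- sqrt(norm(fa$A - astar, "F")^2 + norm(fa$B - bstar, "F")^2) /
    sqrt(norm(astar, "F")^2 + norm(bstar, "F")^2)
  expect_lt(err, 1e-4)
})

test_that("full additive reduces to plain addition and detects head-only maps", {
  set.seed(59)
  d <- 6
  m <- matrix(runif(20 * d), 20, d)
  h <- matrix(runif(20 * d), 20, d)
  fa <- fit_full_additive(m, h, m + h, lambda = 1e-9)
  expect_lt(max(abs(fa$A - diag(d))), 1e-5)
  expect_lt(max(abs(fa$B - diag(d))), 1e-5)

  bstar <- matrix(rnorm(d * d), d, d)
  p <- t(bstar %*% t(h))
  fa2 <- fit_full_additive(m, h, p, lambda = 1e-6)
  expect_lt(norm(fa2$B - bstar, "F") / norm(bstar, "F"), 1e-3)
  expect_lt(norm(fa2$A, "F"), 1e-2 * norm(fa2$B, "F"))
})

test_that("ridge at lambda = 0 equals the unregularized least-squares oracle", {
  set.seed(61)
  h <- matrix(rnorm(40), 20, 2)
  p <- matrix(rnorm(40), 20, 2)
  fit <- fit_lexical_function(h, p, lambda = 0)
  ls <- t(qr.solve(cbind(h, 1), p))   # independent solver route
  expect_equal(unname(fit$matrix), unname(ls), tolerance = 1e-8)
})

test_that("recovery error shrinks with training-set size at fixed noise", {
  set.seed(67)
  d <- 5
  mstar <- matrix(rnorm(d * (d + 1)), d, d + 1)
  mean_err <- function(n_pairs) {
    mean(vapply(1:8, function(r) {
      h <- matrix(runif(n_pairs * d), n_pairs, d)
      p <- t(mstar %*% t(cbind(h, 1))) + matrix(rnorm(n_pairs * d, 0, 0.05),
                                                n_pairs, d)
      fit <- fit_lexical_function(h, p, lambda = 1e-6)
      norm(fit$matrix - mstar, "F") / norm(mstar, "F")
    }, numeric(1)))
  }
  expect_lt(mean_err(200), mean_err(12))
})

test_that("composition baselines follow their definitions", {
  vecs <- rbind(m = c(1, 0), h = c(0, 1), m2 = c(2, 3), h2 = c(4, 0))
  sp <- semantic_space(vecs)
  add <- composition_model("additive")
  mul <- composition_model("multiplicative")
  expect_equal(compose_compound(add, "m", "h", sp), c(1, 1))
  expect_equal(compose_compound(mul, "m2", "h2", sp), c(8, 0))
  # untrained modifier signals uncomposable
  lf <- composition_model("lexical_function",
                          list(m = fit_lexical_function(diag(2), diag(2),
                                                        lambda = 1e-8)))
  expect_null(compose_compound(lf, "unknown", "h", sp))
})

test_that("lexical-function composition is linear in the head vector", {
  set.seed(71)
  d <- 4
  h <- matrix(runif(40), 10, d)
  p <- matrix(runif(40), 10, d)
  fit <- fit_lexical_function(h, p, lambda = 1e-3, intercept = FALSE)
  sp <- semantic_space(matrix(runif(3 * d), 3, d,
                              dimnames = list(c("h1", "h2", "x"), NULL)))
  mod <- composition_model("lexical_function", list(mm = fit))
  h1 <- sp$vectors["h1", ]; h2 <- sp$vectors["h2", ]
  combo <- as.numeric(fit$matrix %*% (2 * h1 + 3 * h2))
  expect_equal(combo,
               2 * as.numeric(fit$matrix %*% h1) +
                 3 * as.numeric(fit$matrix %*% h2),
               tolerance = 1e-10)
})
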