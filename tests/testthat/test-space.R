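test_that("build_vocabulary orders rows by frequency with alphabetical ties", {
  co <- tokenized_corpus(list(rep("a", 5), rep("b", 3), "c"))
  v <- build_vocabulary(co, 2, extra_rows = list("c", c("a", "b")))
  expect_equal(v$rows, c("a", "b", "c", "a b"))
  expect_equal(v$columns, c("a", "b"))
  expect_equal(v$is_bigram, c(FALSE, FALSE, FALSE, TRUE))

  # extra row already in the top-n is not duplicated
  v2 <- build_vocabulary(co, 2, extra_rows = list("a"))
  expect_equal(v2$rows, c("a", "b"))

  # chosen top-n lemmata all at least as frequent as any excluded lemma
  set.seed(5)
  vocab <- paste0("w", sprintf("%03d", 1:100))
  sents <- random_toy_corpus(300, vocab)
  co3 <- tokenized_corpus(sents)
  v3 <- build_vocabulary(co3, 50)
  freq <- table(unlist(sents))
  expect_gte(min(freq[v3$columns]), max(freq[setdiff(names(freq), v3$columns)]))
})

test_that("build_vocabulary warns when n_content exceeds the lexicon", {
  co <- tokenized_corpus(list(c("a", "b")))
  expect_warning(v <- build_vocabulary(co, 10), "exceeds")
  expect_equal(v$columns, c("a", "b"))
})

test_that("windowed counting matches the hand-worked cases", {
  co <- tokenized_corpus(list(c("x", "a", "y")))
  v <- build_vocabulary(co, 3, extra_rows = list())
  cm <- count_cooccurrences(co, v, 1)
  expect_equal(cm$counts["a", "x"], 1)
  expect_equal(cm$counts["a", "y"], 1)

  # sentence boundaries block the window
  co2 <- tokenized_corpus(list(c("x", "a"), "y"))
  cm2 <- count_cooccurrences(co2, build_vocabulary(co2, 3), 2)
  expect_equal(cm2$counts["a", "y"], 0)
})

test_that("windowed counting equals the brute-force recount on random corpora", {
  set.seed(17)
  vocab <- c(letters[1:12])
  for (rep in 1:6) {
    sents <- random_toy_corpus(80, vocab)
    co <- tokenized_corpus(sents)
    v <- build_vocabulary(co, 8,
                          extra_rows = list(c("a", "b"), c("c", "d"), "z"))
    for (w in c(1L, 2L, 3L)) {
      got <- as.matrix(count_cooccurrences(co, v, w)$counts)
      want <- oracle_cooccurrence(co$sentences, v$rows, v$columns, w)
      expect_equal(got, want + 0, ignore_attr = FALSE)
    }
  }
})

test_that("ppmi matches hand computation and the per-cell oracle", {
  m <- matrix(c(10, 0, 0, 10), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(as.matrix(ppmi(m)),
               matrix(c(log(2), 0, 0, log(2)), 2, 2,
                      dimnames = dimnames(m)))

  # all-equal counts are independent: PPMI identically zero
  u <- matrix(3, 4, 5, dimnames = list(paste0("r", 1:4), paste0("c", 1:5)))
  expect_true(all(as.matrix(ppmi(u)) == 0))

  set.seed(23)
  for (rep in 1:10) {
    cnt <- matrix(rpois(30, 2), 6, 5,
                  dimnames = list(paste0("r", 1:6), paste0("c", 1:5)))
    if (sum(cnt) == 0) next
    expect_equal(as.matrix(ppmi(cnt)), oracle_ppmi(cnt), tolerance = 1e-12)
  }

  expect_error(ppmi(matrix(0, 2, 2)), "degenerate")
})

test_that("ppmi is non-negative and zero wherever the count is zero", {
  set.seed(29)
  cnt <- matrix(rpois(48, 1), 8, 6,
                dimnames = list(paste0("r", 1:8), paste0("c", 1:6)))
  w <- as.matrix(ppmi(cnt))
  expect_true(all(w >= 0))
  expect_true(all(w[cnt == 0] == 0))
})

test_that("cosine reproduces the worked example and basic identities", {
  expect_equal(round(cosine(c(2, 5, 3), c(3, 1, 5)), 2), 0.71)
  v <- c(0.3, 1.2, 0.01)
  expect_equal(cosine(v, v), 1.0)
  expect_equal(cosine(c(1, 0, 0), c(0, 1, 0)), 0.0)
  expect_error(cosine(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("cosine is symmetric, scale-invariant and bounded for non-negative input", {
  set.seed(31)
  for (i in 1:20) {
    a <- runif(8); b <- runif(8)
    expect_equal(cosine(a, b), cosine(b, a))
    expect_equal(cosine(3.7 * a, b), cosine(a, b))
    expect_gte(cosine(a, b), 0)
    expect_lte(cosine(a, b), 1 + 1e-12)
  }
})

test_that("reduce_dimensions recovers exact low rank, is seeded, monotone in d", {
  set.seed(37)
  x <- outer(runif(12, 0.1, 1), runif(9, 0.1, 1))   # exact rank 1
  s <- reduce_dimensions(x, 1, seed = 99)
  expect_lt(s$provenance$relative_error, 1e-6)
  expect_true(all(s$vectors >= 0))

  s2 <- reduce_dimensions(x, 1, seed = 99)
  expect_identical(s$vectors, s2$vectors)

  y <- matrix(runif(60 * 40), 60, 40)
  y[y < 0.6] <- 0                                    # PPMI-like sparsity
  e10 <- reduce_dimensions(y, 10, seed = 1)$provenance$relative_error
  e20 <- reduce_dimensions(y, 20, seed = 1)$provenance$relative_error
  expect_lte(e20, e10 + 1e-8)

  expect_error(reduce_dimensions(y, 100, seed = 1), "rank")
})

test_that("nearest_neighbours matches the exhaustive-sort oracle", {
  set.seed(41)
  vecs <- matrix(runif(50 * 6), 50, 6)
  rownames(vecs) <- c(paste0("w", 1:45), paste("big", 1:5))  # 5 bigram rows
  sp <- semantic_space(vecs)
  v <- runif(6)
  for (k in c(1, 7, 20)) {
    got <- nearest_neighbours(sp, v, k)
    want <- oracle_nearest(vecs, v, k)
    expect_equal(got$target, want$target)
    expect_equal(got$cosine, want$cosine)
  }
  # prefix property
  n7 <- nearest_neighbours(sp, v, 7)
  n8 <- nearest_neighbours(sp, v, 8)
  expect_equal(n8$target[1:7], n7$target)
})

test_that("nearest_neighbours honours exclusion, ties and k bounds", {
  vecs <- diag(5); rownames(vecs) <- paste0("w", 1:5)
  sp <- semantic_space(vecs)
  nn <- nearest_neighbours(sp, c(1, 0, 0, 0, 0), 1, exclude = "w1")
  expect_equal(nn$target, "w2")   # all-tied at 0: first row order wins
  expect_error(nearest_neighbours(sp, c(1, 0, 0, 0, 0), 10), "eligible")

  same <- matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE)
  rownames(same) <- paste0("v", 1:4)
  nn3 <- nearest_neighbours(semantic_space(same), c(1, 2, 3), 3)
  expect_equal(nn3$cosine, rep(1, 3))
})

test_that("space export/import round-trips vectors and provenance", {
  x <- matrix(runif(20), 5, 4, dimnames = list(paste0("w", 1:5), NULL))
  sp <- semantic_space(x, provenance = list(method = "nmf-multiplicative",
                                            d = 4L, seed = 3L,
                                            relative_error = 0.12))
  tf <- withr::local_tempfile()
  export_space(sp, tf)
  back <- import_space(tf)
  expect_equal(unname(back$vectors), unname(x), tolerance = 1e-12)
  expect_equal(rownames(back$vectors), rownames(x))
  expect_equal(back$provenance$seed, 3L)
  file.remove(paste0(tf, ".provenance.dcf"))
})
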