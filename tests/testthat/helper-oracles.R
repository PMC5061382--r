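# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals.

# naive triple-loop windowed co-occurrence recount, including bigram rows
oracle_cooccurrence <- function(sentences, rows, columns, half_window) {
  uni <- rows[!grepl(" ", rows)]
  bi <- rows[grepl(" ", rows)]
  out <- matrix(0L, length(rows), length(columns),
                dimnames = list(rows, columns))
  for (s in sentences) {
    n <- length(s)
    for (i in seq_len(n)) {
      if (s[i] %in% uni) {
        for (j in seq_len(n)) {
          if (j != i && abs(j - i) <= half_window && s[j] %in% columns) {
            out[s[i], s[j]] <- out[s[i], s[j]] + 1L
          }
        }
      }
      if (i < n) {
        key <- paste(s[i], s[i + 1L])
        if (key %in% bi) {
          ctx <- c(seq(i - half_window, i - 1L),
                   seq(i + 2L, i + 1L + half_window))
          for (j in ctx) {
            if (j >= 1L && j <= n && s[j] %in% columns) {
              out[key, s[j]] <- out[key, s[j]] + 1L
            }
          }
        }
      }
    }
  }
  out
}

# per-cell PPMI formula evaluation
oracle_ppmi <- function(counts) {
  total <- sum(counts)
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  rs <- rowSums(counts); cs <- colSums(counts)
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      if (counts[i, j] > 0) {
        pmi <- log((counts[i, j] / total) / ((rs[i] / total) * (cs[j] / total)))
        out[i, j] <- max(0, pmi)
      }
    }
  }
  out
}

# exhaustive-sort nearest neighbours (stable in row order)
oracle_nearest <- function(vectors, v, k, exclude = character(0)) {
  eligible <- which(!grepl(" ", rownames(vectors)) &
                      !(rownames(vectors) %in% exclude))
  cs <- vapply(eligible, function(i) {
    a <- vectors[i, ]
    den <- sqrt(sum(a^2)) * sqrt(sum(v^2))
    if (den == 0) -Inf else sum(a * v) / den
  }, numeric(1))
  ord <- order(-cs, seq_along(cs))[seq_len(k)]
  data.frame(target = rownames(vectors)[eligible[ord]], cosine = cs[ord],
             stringsAsFactors = FALSE)
}

# random toy corpus for counting oracles
random_toy_corpus <- function(n_sentences, vocab, min_len = 2L, max_len = 9L) {
  lapply(seq_len(n_sentences), function(i) {
    sample(vocab, sample(min_len:max_len, 1L), replace = TRUE)
  })
}

covariate_names <- function() {
  c("modifier_length", "head_length", "log_pair_freq", "log_rev_pair_freq",
    "log_modifier_freq", "log_head_freq", "pmi",
    "modifier_family_size", "head_family_size")
}

measure_names <- function() {
  c("head_proximity", "modifier_proximity", "constituent_similarity",
    "neighbourhood_density", "entropy")
}
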