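#' Synthetic corpus configuration
#'
#' Describes the topic-mixture generative model used by
#' \code{\link{generate_corpus}}: every lemma has a latent topic profile,
#' ordinary sentences draw a topic and then words from its word distribution,
#' and a configurable fraction of sentences embeds a "modifier head" bigram
#' whose surrounding context words are drawn from the distribution obtained by
#' applying the modifier's planted linear transform to the head's topic
#' mixture. Defaults give a corpus whose full pipeline run takes minutes on
#' one CPU.
#'
#' @param vocab_size number of lemma types (default 500).
#' @param n_topics number of latent topics (default 8).
#' @param n_sentences number of sentences (default 30000).
#' @param min_length,mean_extra sentence length is
#'   \code{min_length + Poisson(mean_extra)} (defaults 3 and 6).
#' @param n_modifiers number of designated modifier lemmata (default 6).
#' @param n_heads number of head-noun lemmata compounds draw from (default 40).
#' @param compound_rate probability that a sentence embeds a compound bigram
#'   (default 0.15).
#' @param n_item_pairs number of attested item pairs; their reversals are
#'   added automatically (default 60).
#' @param topic_concentration Dirichlet concentration of the topic-word
#'   distributions (default 0.08; small values give distinct topics).
#' @param seed integer seed.
#' @return an object of class \code{corpus_config}.
#' @export
corpus_config <- function(vocab_size = 500L, n_topics = 8L,
                          n_sentences = 30000L, min_length = 3L,
                          mean_extra = 6, n_modifiers = 6L, n_heads = 40L,
                          compound_rate = 0.15, n_item_pairs = 60L,
                          topic_concentration = 0.08, seed = 1L) {
  stopifnot(compound_rate >= 0, compound_rate < 1,
            n_modifiers >= 1 || compound_rate == 0,
            vocab_size >= n_modifiers + n_heads + 10)
  structure(as.list(environment()), class = "corpus_config")
}

make_lexicon <- function(n) {
  # distinct pronounceable-ish pseudo-lemmata, 3-8 letters
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    syl <- replicate(n, paste0(
      sample(cons, 1), sample(vow, 1),
      sample(c("", paste0(sample(cons, 2), sample(vow, 2))), 1, prob = c(.3, rep(.35, 2)))
    ))
    more <- paste0(syl, sample(c("", cons), n, replace = TRUE))
    out <- unique(c(out, more[nchar(more) >= 3 & nchar(more) <= 8]))
  }
  out[seq_len(n)]
}

#' Generate a synthetic corpus with known ground truth
#'
#' @param config a \code{\link{corpus_config}}.
#' @return list with \code{corpus} (a \code{tokenized_corpus}) and
#'   \code{ledger}: unigram and adjacent-bigram counts of the emitted corpus,
#'   the planted per-modifier transforms, the topic-word matrix and per-word
#'   topic mixtures, modifier and head sets, item pairs (attested plus
#'   reversed), per-pair context distributions, and the configuration.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  if (config$compound_rate > 0 && config$n_modifiers < 1) {
    stop("infeasible configuration: positive compound rate with no modifiers")
  }
  with_preserved_seed(config$seed, {
    V <- config$vocab_size; Tt <- config$n_topics
    lexicon <- make_lexicon(V)
    modifiers <- lexicon[seq_len(config$n_modifiers)]
    heads <- lexicon[config$n_modifiers + seq_len(config$n_heads)]

    # topic-word matrix: V x T, columns are word distributions per topic
    phi <- vapply(seq_len(Tt), function(t) rdirichlet1(V, config$topic_concentration),
                  numeric(V))
    rownames(phi) <- lexicon
    # word topic mixtures (row-normalized phi)
    theta <- phi / pmax(rowSums(phi), .Machine$double.eps)
    topic_weights <- rdirichlet1(Tt, 5)

    # planted per-modifier transforms on topic mixtures (column-stochastic)
    transforms <- lapply(seq_len(config$n_modifiers), function(i) {
      a <- diag(0.25, Tt) + matrix(stats::rgamma(Tt * Tt, shape = 0.3), Tt, Tt)
      sweep(a, 2, colSums(a), "/")
    })
    names(transforms) <- modifiers

    # item pairs: attested pairs plus their reversals
    ip_mod <- sample(modifiers, config$n_item_pairs, replace = TRUE)
    ip_head <- sample(heads, config$n_item_pairs, replace = TRUE)
    dup <- duplicated(paste(ip_mod, ip_head))
    item_pairs <- data.frame(
      modifier = c(ip_mod[!dup], ip_head[!dup]),
      head = c(ip_head[!dup], ip_mod[!dup]),
      attested = rep(c(TRUE, FALSE), each = sum(!dup)),
      stringsAsFactors = FALSE
    )

    n <- config$n_sentences
    lens <- config$min_length + stats::rpois(n, config$mean_extra)
    is_comp <- stats::runif(n) < config$compound_rate &
      config$n_modifiers > 0

    sentences <- vector("list", n)

    # ordinary sentences, grouped by sampled topic
    plain_idx <- which(!is_comp)
    z <- sample.int(Tt, length(plain_idx), replace = TRUE,
                    prob = topic_weights)
    for (t in seq_len(Tt)) {
      idx <- plain_idx[z == t]
      if (!length(idx)) next
      tot <- sum(lens[idx])
      words <- sample(lexicon, tot, replace = TRUE, prob = phi[, t])
      sentences[idx] <- split(words, rep.int(seq_along(idx), lens[idx]))
    }

    # compound sentences, grouped by (modifier, head); head sampled with a
    # rank-frequency skew so pair frequencies vary around the filters
    comp_idx <- which(is_comp)
    pair_ctx <- list()
    if (length(comp_idx)) {
      mi <- sample.int(config$n_modifiers, length(comp_idx), replace = TRUE)
      head_w <- 1 / seq_len(config$n_heads)
      hi <- sample.int(config$n_heads, length(comp_idx), replace = TRUE,
                       prob = head_w)
      grp <- paste(mi, hi)
      for (g in unique(grp)) {
        sel <- comp_idx[grp == g]
        m_id <- mi[match(g, grp)]; h_id <- hi[match(g, grp)]
        md <- modifiers[m_id]; hd <- heads[h_id]
        mixed <- as.numeric(transforms[[md]] %*% theta[hd, ])
        mixed <- mixed / sum(mixed)
        q <- as.numeric(phi %*% mixed)
        q <- q / sum(q)
        pair_ctx[[bigram_key(md, hd)]] <- q
        l <- lens[sel]
        tot <- sum(l) - 2L * length(sel)
        ctx <- sample(lexicon, tot, replace = TRUE, prob = q)
        ctx_split <- split(ctx, rep.int(seq_along(sel), l - 2L))
        pos <- vapply(l, function(li) sample.int(li - 1L, 1L), integer(1))
        sentences[sel] <- lapply(seq_along(sel), function(k) {
          s <- ctx_split[[k]]
          append(s, c(md, hd), after = pos[k] - 1L)
        })
      }
    }

    corpus <- tokenized_corpus(sentences)
    ledger <- list(
      config = config,
      lexicon = lexicon,
      modifiers = modifiers,
      heads = heads,
      transforms = transforms,
      phi = phi,
      theta = theta,
      topic_weights = topic_weights,
      item_pairs = item_pairs,
      pair_context_dists = pair_ctx,
      n_sentences = length(corpus$sentences),
      n_compound_sentences = length(comp_idx),
      unigram_counts = lemma_frequencies(corpus),
      bigram_counts = corpus_bigram_counts(corpus)
    )
    list(corpus = corpus, ledger = ledger)
  })
}

#' Synthetic ratings configuration
#'
#' Describes the known generating model for plausibility ratings: a smooth
#' surface over the measure columns, Gaussian random intercepts for modifier
#' and head lemmata, Gaussian residual noise, and clamping to the rating
#' scale.
#'
#' @param surface preset name (\code{"te_hp_mp"}: a ridge rising in head
#'   proximity and peaked at medium modifier proximity — a genuinely
#'   non-additive, non-bilinear surface; \code{"linear_hp"}: a linear
#'   head-proximity effect; \code{"null"}: a constant) or a function of the
#'   measure-table data.frame returning the surface values.
#' @param re_sd_modifier,re_sd_head random-intercept standard deviations
#'   (defaults 0.2).
#' @param noise_sd residual standard deviation (default 0.35).
#' @param scale rating scale bounds (default \code{c(0, 4)}).
#' @param seed integer seed.
#' @return an object of class \code{ratings_config}.
#' @export
ratings_config <- function(surface = "te_hp_mp", re_sd_modifier = 0.2,
                           re_sd_head = 0.2, noise_sd = 0.35,
                           scale = c(0, 4), seed = 1L) {
  stopifnot(noise_sd > 0, length(scale) == 2L, scale[1] < scale[2])
  structure(as.list(environment()), class = "ratings_config")
}

surface_function <- function(surface) {
  if (is.function(surface)) return(surface)
  switch(surface,
    # a ridge rising in head proximity whose height is peaked at medium
    # modifier proximity: high plausibility needs a clear head contribution
    # and a clear-but-not-redundant modifier contribution
    te_hp_mp = function(df) {
      1.3 + 1.6 * df$head_proximity *
        exp(-(df$modifier_proximity - 0.55)^2 / (2 * 0.18^2))
    },
    linear_hp = function(df) 1.5 + 1.0 * df$head_proximity,
    null = function(df) rep(2, nrow(df)),
    stop("unknown surface preset: ", surface)
  )
}

#' Simulate a measure table with realistic marginals
#'
#' Draws the five plausibility-measure columns, the frequency covariates and
#' constituent factor labels for \code{n} items, without running the corpus
#' pipeline. Family sizes are generated correlated with the respective
#' log frequencies, mirroring the collinearity the covariate screen must
#' handle.
#'
#' @param n number of items.
#' @param n_modifiers,n_heads number of distinct constituent lemmata
#'   (defaults 60 each).
#' @param seed integer seed.
#' @return data.frame with measure, covariate and factor columns.
#' @export
simulate_measure_table <- function(n, n_modifiers = 60L, n_heads = 60L,
                                   seed = 1L) {
  with_preserved_seed(seed, {
    attested <- stats::runif(n) < 0.5
    log_pair_freq <- ifelse(attested, stats::rexp(n, rate = 0.7),
                            stats::rexp(n, rate = 8))
    log_modifier_freq <- stats::runif(n, 2, 9)
    log_head_freq <- stats::runif(n, 2, 9)
    data.frame(
      modifier = paste0("mod", sample.int(n_modifiers, n, replace = TRUE)),
      head = paste0("head", sample.int(n_heads, n, replace = TRUE)),
      attested = attested,
      head_proximity = stats::rbeta(n, 2.5, 2.5),
      modifier_proximity = stats::rbeta(n, 2.5, 2.5),
      constituent_similarity = stats::rbeta(n, 2, 2),
      neighbourhood_density = 0.8 * stats::rbeta(n, 5, 3),
      entropy = stats::runif(n, 4.5, 5.7),
      modifier_length = sample(3:10, n, replace = TRUE),
      head_length = sample(3:10, n, replace = TRUE),
      log_pair_freq = log_pair_freq,
      log_rev_pair_freq = stats::rexp(n, rate = 8),
      log_modifier_freq = log_modifier_freq,
      log_head_freq = log_head_freq,
      pmi = stats::rnorm(n, 0.5, 1),
      modifier_family_size = pmax(0L, as.integer(round(
        3 * log_modifier_freq + stats::rnorm(n, 0, 2)))),
      head_family_size = pmax(0L, as.integer(round(
        3 * log_head_freq + stats::rnorm(n, 0, 2)))),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate ratings over a measure table
#'
#' rating = clamp(surface(measures) + modifier intercept + head intercept +
#' noise, scale). Random intercepts are drawn once per factor level.
#'
#' @param config a \code{\link{ratings_config}}.
#' @param measure_table data.frame with the five measure columns,
#'   \code{log_pair_freq}, and \code{modifier} / \code{head} labels.
#' @return the measure table with a \code{rating} column appended; the ground
#'   truth (surface values, intercept draws, noise draws) is attached as the
#'   \code{"ground_truth"} attribute.
#' @export
generate_ratings <- function(config, measure_table) {
  stopifnot(inherits(config, "ratings_config"))
  needed <- c("head_proximity", "modifier_proximity",
              "constituent_similarity", "neighbourhood_density", "entropy",
              "log_pair_freq", "modifier", "head")
  miss <- setdiff(needed, names(measure_table))
  if (length(miss)) stop("measure table lacks columns: ",
                         paste(miss, collapse = ", "))
  with_preserved_seed(config$seed, {
    f <- surface_function(config$surface)
    surf <- f(measure_table)
    mods <- unique(measure_table$modifier)
    heads <- unique(measure_table$head)
    b_mod <- stats::setNames(stats::rnorm(length(mods), 0,
                                          config$re_sd_modifier), mods)
    b_head <- stats::setNames(stats::rnorm(length(heads), 0,
                                           config$re_sd_head), heads)
    noise <- stats::rnorm(nrow(measure_table), 0, config$noise_sd)
    raw <- surf + b_mod[measure_table$modifier] +
      b_head[measure_table$head] + noise
    out <- measure_table
    out$rating <- clamp(unname(raw), config$scale[1], config$scale[2])
    attr(out, "ground_truth") <- list(
      surface = surf, surface_function = f,
      modifier_intercepts = b_mod, head_intercepts = b_head,
      noise = noise, config = config
    )
    out
  })
}
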