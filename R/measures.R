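#' Semantic transparency measures of a composed compound
#'
#' Head proximity is the cosine between the composed vector and the head
#' vector; modifier proximity the cosine between the composed vector and the
#' modifier vector; constituent similarity the cosine between modifier and
#' head vectors.
#'
#' @param composed,m,h numeric vectors of equal length (composed compound,
#'   modifier, head).
#' @return named list with \code{head_proximity}, \code{modifier_proximity},
#'   \code{constituent_similarity}; all NA (with attribute
#'   \code{undefined = TRUE}) if any input has zero norm.
#' @export
transparency_measures <- function(composed, m, h) {
  stopifnot(length(composed) == length(h), length(m) == length(h))
  if (sum(composed^2) == 0 || sum(m^2) == 0 || sum(h^2) == 0) {
    out <- list(head_proximity = NA_real_, modifier_proximity = NA_real_,
                constituent_similarity = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  list(head_proximity = cosine(composed, h),
       modifier_proximity = cosine(composed, m),
       constituent_similarity = cosine(m, h))
}

#' Neighbourhood density
#'
#' Mean cosine similarity between a vector and its \code{k} nearest
#' single-lemma neighbours in the space.
#'
#' @param space a \code{semantic_space}.
#' @param v query vector.
#' @param k neighbourhood size (default 20).
#' @param exclude row targets to exclude from the neighbourhood (by default
#'   none; constituents are not excluded).
#' @return mean cosine of the k nearest neighbours.
#' @export
neighbourhood_density <- function(space, v, k = 20L, exclude = character(0)) {
  nn <- nearest_neighbours(space, v, k, exclude = exclude)
  mean(nn$cosine)
}

#' Vector entropy
#'
#' Uniformity measure of a non-negative vector:
#' \code{log(n) - (1/n) * sum(p_i log p_i)} after normalizing the vector to
#' sum 1, with \code{0 log 0 := 0} and natural logarithms. Values are highest
#' for near-uniform vectors and lower for peaked ones. Negative entries are
#' clipped to zero with a warning.
#'
#' @param v numeric vector of length >= 2 with at least one positive entry.
#' @return the entropy value, or NA with attribute \code{undefined} if no
#'   entry is positive.
#' @export
vector_entropy <- function(v) {
  n <- length(v)
  stopifnot(n >= 2)
  if (any(v < 0)) {
    warning("negative entries clipped to 0 before entropy")
    v <- pmax(v, 0)
  }
  s <- sum(v)
  if (s <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  p <- v / s
  plogp <- ifelse(p > 0, p * log(p), 0)
  log(n) - sum(plogp) / n
}

#' Frequency table from a corpus
#'
#' Unigram and ordered adjacent-bigram token counts, the backing store for the
#' frequency covariates. A table built from any source (e.g. a subtitle-corpus
#' export read with \code{\link{read_frequency_table}}) can be used
#' interchangeably.
#'
#' @param corpus a \code{tokenized_corpus}.
#' @param source_tag short label recorded with the table.
#' @return an object of class \code{frequency_table}: \code{unigrams} (named
#'   integer vector), \code{bigrams} (data.table modifier/head/freq),
#'   \code{total_unigrams}, \code{total_bigrams}, \code{source}.
#' @export
frequency_table <- function(corpus, source_tag = "corpus") {
  uni <- lemma_frequencies(corpus)
  bi <- corpus_bigram_counts(corpus)
  structure(
    list(unigrams = uni, bigrams = bi,
         total_unigrams = sum(uni), total_bigrams = sum(bi$freq),
         source = source_tag),
    class = "frequency_table"
  )
}

#' Read a frequency table from delimited text
#'
#' Expects a header and columns \code{term} (one word, or two words separated
#' by a space for bigrams) and \code{count}.
#'
#' @param path tab- or comma-delimited text file.
#' @param sep field separator (default tab).
#' @param source_tag label recorded with the table.
#' @return a \code{frequency_table}.
#' @export
read_frequency_table <- function(path, sep = "\t", source_tag = basename(path)) {
  tab <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("term", "count") %in% names(tab)))
  term <- tolower(tab$term)
  bi <- is_bigram_target(term)
  uni <- stats::setNames(as.integer(tab$count[!bi]), term[!bi])
  parts <- strsplit(term[bi], " ", fixed = TRUE)
  bigrams <- data.table(
    modifier = vapply(parts, `[`, character(1), 1L),
    head = vapply(parts, `[`, character(1), 2L),
    freq = as.integer(tab$count[bi])
  )
  structure(
    list(unigrams = uni, bigrams = bigrams,
         total_unigrams = sum(uni), total_bigrams = sum(bigrams$freq),
         source = source_tag),
    class = "frequency_table"
  )
}

freq_lookup_unigram <- function(freqs, w) {
  out <- freqs$unigrams[w]
  out[is.na(out)] <- 0L
  unname(out)
}

freq_lookup_bigram <- function(freqs, modifier, head) {
  key <- bigram_key(modifier, head)
  tabkey <- bigram_key(freqs$bigrams$modifier, freqs$bigrams$head)
  out <- freqs$bigrams$freq[match(key, tabkey)]
  out[is.na(out)] <- 0L
  out
}

#' Lexical covariates of an item
#'
#' Letter lengths of both constituents; Laplace-transformed natural-log
#' frequencies \code{log(count + 1)} of the modifier, the head, the ordered
#' pair and the reversed pair; pointwise mutual information between the two
#' constituents (from the +1-smoothed unigram and ordered-bigram
#' probabilities); and family sizes (number of distinct bigram types with the
#' word in the respective constituent slot).
#'
#' @param modifier,head item lemmata (vectorized).
#' @param freqs a \code{frequency_table}.
#' @return data.frame with columns \code{modifier_length}, \code{head_length},
#'   \code{log_pair_freq}, \code{log_rev_pair_freq}, \code{log_modifier_freq},
#'   \code{log_head_freq}, \code{pmi}, \code{modifier_family_size},
#'   \code{head_family_size}.
#' @export
item_covariates <- function(modifier, head, freqs) {
  stopifnot(inherits(freqs, "frequency_table"), length(modifier) == length(head))
  modifier <- tolower(modifier); head <- tolower(head)
  c_m <- freq_lookup_unigram(freqs, modifier)
  c_h <- freq_lookup_unigram(freqs, head)
  c_mh <- freq_lookup_bigram(freqs, modifier, head)
  c_hm <- freq_lookup_bigram(freqs, head, modifier)

  n_uni <- max(freqs$total_unigrams, 1L)
  n_bi <- max(freqs$total_bigrams, 1L)
  pmi <- log(c_mh + 1) - log(n_bi) - (log(c_m + 1) - log(n_uni)) -
    (log(c_h + 1) - log(n_uni))

  fam_mod <- vapply(modifier, function(w) sum(freqs$bigrams$modifier == w),
                    integer(1))
  fam_head <- vapply(head, function(w) sum(freqs$bigrams$head == w),
                     integer(1))

  data.frame(
    modifier_length = nchar(modifier),
    head_length = nchar(head),
    log_pair_freq = log(c_mh + 1),
    log_rev_pair_freq = log(c_hm + 1),
    log_modifier_freq = log(c_m + 1),
    log_head_freq = log(c_h + 1),
    pmi = pmi,
    modifier_family_size = unname(fam_mod),
    head_family_size = unname(fam_head),
    stringsAsFactors = FALSE
  )
}

#' Read an item table
#'
#' Delimited text with a header and at least the columns \code{modifier},
#' \code{head}, \code{rating}; an optional \code{attested} column (logical or
#' 0/1) marks attested vs reversed-order pairs.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data.frame of items.
#' @export
read_item_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("modifier", "head", "rating") %in% names(tab)))
  tab$modifier <- tolower(tab$modifier)
  tab$head <- tolower(tab$head)
  if (is.null(tab$attested)) tab$attested <- NA
  tab$attested <- as.logical(tab$attested)
  tab
}

#' Assemble the per-item analysis table
#'
#' Composes a vector for every item, computes the five plausibility measures
#' and the lexical covariates, and returns one row per item. Items whose
#' modifier has no fitted lexical function, or whose constituents lack space
#' vectors, are marked excluded with a reason and get NA measures.
#'
#' @param items data.frame with columns \code{modifier} and \code{head};
#'   \code{rating} and \code{attested} are carried through when present
#'   (ratings may instead be attached later, e.g. by
#'   \code{\link{generate_ratings}}).
#' @param space a \code{semantic_space}.
#' @param model a \code{composition_model}.
#' @param freqs a \code{frequency_table}.
#' @param k neighbourhood size for neighbourhood density (default 20).
#' @return data.frame: the item columns plus \code{head_proximity},
#'   \code{modifier_proximity}, \code{constituent_similarity},
#'   \code{neighbourhood_density}, \code{entropy}, the covariate columns,
#'   \code{excluded} and \code{exclusion_reason}. Composed vectors are
#'   attached as the \code{"composed"} attribute (a list).
#' @export
assemble_item_table <- function(items, space, model, freqs, k = 20L) {
  stopifnot(is.data.frame(items),
            all(c("modifier", "head") %in% names(items)))
  n <- nrow(items)
  meas <- data.frame(
    head_proximity = rep(NA_real_, n), modifier_proximity = NA_real_,
    constituent_similarity = NA_real_, neighbourhood_density = NA_real_,
    entropy = NA_real_
  )
  excluded <- logical(n)
  reason <- character(n)
  composed_list <- vector("list", n)

  for (i in seq_len(n)) {
    md <- tolower(items$modifier[i]); hd <- tolower(items$head[i])
    mv <- space_vector(space, md)
    hv <- space_vector(space, hd)
    if (is.null(mv) || is.null(hv)) {
      excluded[i] <- TRUE
      reason[i] <- "constituent missing from space"
      next
    }
    cv <- tryCatch(compose_compound(model, md, hd, space),
                   error = function(e) NULL)
    if (is.null(cv)) {
      excluded[i] <- TRUE
      reason[i] <- "no lexical function for modifier"
      next
    }
    composed_list[[i]] <- cv
    tm <- transparency_measures(cv, mv, hv)
    if (isTRUE(attr(tm, "undefined"))) {
      excluded[i] <- TRUE
      reason[i] <- "zero-norm vector"
      next
    }
    meas$head_proximity[i] <- tm$head_proximity
    meas$modifier_proximity[i] <- tm$modifier_proximity
    meas$constituent_similarity[i] <- tm$constituent_similarity
    meas$neighbourhood_density[i] <- neighbourhood_density(space, cv, k = k)
    en <- suppressWarnings(vector_entropy(cv))
    meas$entropy[i] <- if (isTRUE(attr(en, "undefined"))) NA_real_ else en
  }

  covs <- item_covariates(items$modifier, items$head, freqs)
  out <- cbind(items, meas, covs,
               data.frame(excluded = excluded, exclusion_reason = reason,
                          stringsAsFactors = FALSE))
  attr(out, "composed") <- composed_list
  out
}
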