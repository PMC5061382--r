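#' @importFrom data.table data.table := .N setorder
NULL

bigram_key <- function(modifier, head) paste(modifier, head)

is_bigram_target <- function(x) grepl(" ", x, fixed = TRUE)

#' Corpus lemma frequencies
#'
#' @param corpus a \code{tokenized_corpus}.
#' @return named integer vector of lemma token frequencies, decreasing, with
#'   frequency ties broken alphabetically.
#' @export
lemma_frequencies <- function(corpus) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  tab <- table(unlist(corpus$sentences, use.names = FALSE))
  freq <- as.integer(tab)
  names(freq) <- names(tab)
  freq[order(-freq, names(freq), method = "radix")]
}

#' Build the row/column vocabulary of a semantic space
#'
#' Rows are the \code{n_content} most frequent lemmata in the corpus plus any
#' requested extra targets (single lemmata or bigrams given as two-element
#' character vectors); columns (the context dimensions) are the top
#' \code{n_content} lemmata only. Frequency ties are broken alphabetically.
#'
#' @param corpus a \code{tokenized_corpus}.
#' @param n_content number of most-frequent lemmata to use.
#' @param extra_rows list whose elements are single lemmata (length-1
#'   character) or bigrams (length-2 character vectors, modifier then head).
#' @return an object of class \code{space_vocabulary} with fields \code{rows}
#'   (character keys, bigrams space-joined), \code{is_bigram}, \code{columns}.
#' @export
build_vocabulary <- function(corpus, n_content, extra_rows = list()) {
  stopifnot(inherits(corpus, "tokenized_corpus"), n_content >= 1)
  freq <- lemma_frequencies(corpus)
  if (n_content > length(freq)) {
    warning(sprintf("n_content = %d exceeds the %d distinct lemmata; using all",
                    n_content, length(freq)))
    n_content <- length(freq)
  }
  top <- names(freq)[seq_len(n_content)]

  extras <- vapply(extra_rows, function(e) {
    e <- tolower(as.character(e))
    if (length(e) == 1L) e
    else if (length(e) == 2L) bigram_key(e[1L], e[2L])
    else stop("extra_rows elements must have length 1 or 2")
  }, character(1))
  rows <- c(top, setdiff(extras, top))
  rows <- rows[!duplicated(rows)]

  structure(
    list(rows = rows,
         is_bigram = is_bigram_target(rows),
         columns = top),
    class = "space_vocabulary"
  )
}

#' @export
print.space_vocabulary <- function(x, ...) {
  cat(sprintf("space_vocabulary: %d rows (%d bigram), %d context columns\n",
              length(x$rows), sum(x$is_bigram), length(x$columns)))
  invisible(x)
}
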