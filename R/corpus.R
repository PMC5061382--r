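#' Tokenized corpus
#'
#' A lightweight container for a lemmatized, sentence-segmented corpus: a list
#' of sentences, each an ordered character vector of lowercased lemma tokens.
#' Empty sentences are dropped on construction.
#'
#' @param sentences list of character vectors (one per sentence).
#' @return an object of class \code{tokenized_corpus} with fields
#'   \code{sentences} and \code{token_count}.
#' @export
tokenized_corpus <- function(sentences) {
  stopifnot(is.list(sentences))
  sentences <- lapply(sentences, as.character)
  sentences <- sentences[vapply(sentences, length, integer(1)) > 0L]
  structure(
    list(sentences = sentences,
         token_count = sum(vapply(sentences, length, integer(1)))),
    class = "tokenized_corpus"
  )
}

#' @export
print.tokenized_corpus <- function(x, ...) {
  cat(sprintf("tokenized_corpus: %d sentences, %d tokens\n",
              length(x$sentences), x$token_count))
  invisible(x)
}

#' Read a corpus file
#'
#' Reads a plain-text corpus with one sentence per line and whitespace-separated
#' lemma tokens. The \code{"lemma_pos"} dialect additionally strips a trailing
#' \code{"_POS"} tag from each token (e.g. \code{"Moon_NN"} becomes
#' \code{"moon"}). All tokens are lowercased; empty lines are skipped.
#'
#' @param path path to a UTF-8 text file.
#' @param dialect \code{"plain"} or \code{"lemma_pos"}.
#' @return a \code{\link{tokenized_corpus}}.
#' @export
read_corpus <- function(path, dialect = c("plain", "lemma_pos")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("corpus file not found: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty corpus: no sentences in ", path)
  }
  sents <- strsplit(trimws(lines), "[[:space:]]+")
  if (dialect == "lemma_pos") {
    sents <- lapply(sents, function(s) sub("_[^_]*$", "", s))
  }
  sents <- lapply(sents, tolower)
  tokenized_corpus(sents)
}

#' Write a corpus file
#'
#' Inverse of \code{\link{read_corpus}} for the plain dialect: one sentence per
#' line, tokens joined by single spaces.
#'
#' @param corpus a \code{tokenized_corpus}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  writeLines(vapply(corpus$sentences, paste, character(1), collapse = " "),
             path, useBytes = TRUE)
  invisible(path)
}
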