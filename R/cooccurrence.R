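#' Count windowed co-occurrences
#'
#' Slides a symmetric context window of \code{half_window} tokens over every
#' sentence and counts, for each vocabulary row target, how often each context
#' column lemma falls inside the window. Co-occurrences never cross sentence
#' boundaries. Bigram row targets are treated like a single word occupying two
#' adjacent positions: their window extends \code{half_window} tokens to the
#' left of the first member and to the right of the second member, and the
#' member tokens themselves are not counted as their own context. Bigram member
#' tokens still count as ordinary occurrences of the corresponding unigram
#' targets.
#'
#' @param corpus a \code{tokenized_corpus}.
#' @param vocab a \code{space_vocabulary}.
#' @param half_window window half-width in tokens (>= 1).
#' @return an object of class \code{cooccurrence_matrix}: a list with
#'   \code{counts} (a sparse \code{|rows| x |columns|} integer-valued matrix
#'   with dimnames) and \code{vocab}.
#' @export
count_cooccurrences <- function(corpus, vocab, half_window) {
  stopifnot(inherits(corpus, "tokenized_corpus"),
            inherits(vocab, "space_vocabulary"),
            half_window >= 1)
  half_window <- as.integer(half_window)

  ns <- length(corpus$sentences)
  lens <- vapply(corpus$sentences, length, integer(1))
  dt <- data.table(
    sid = rep.int(seq_len(ns), lens),
    token = unlist(corpus$sentences, use.names = FALSE)
  )

  cols <- vocab$columns
  row_index <- stats::setNames(seq_along(vocab$rows), vocab$rows)
  col_index <- stats::setNames(seq_along(cols), cols)

  ii <- integer(0); jj <- integer(0)

  # unigram targets: for each gap o, the ordered token pair (t, t+o) yields a
  # co-occurrence event in both directions
  tok <- dt$token
  sid <- dt$sid
  for (o in seq_len(half_window)) {
    n <- length(tok)
    if (n <= o) next
    a <- tok[seq_len(n - o)]
    b <- tok[seq_len(n - o) + o]
    same <- sid[seq_len(n - o)] == sid[seq_len(n - o) + o]
    # single tokens never collide with bigram row keys (those contain a space)
    ra <- row_index[a]; cb <- col_index[b]
    keep <- same & !is.na(ra) & !is.na(cb)
    ii <- c(ii, unname(ra[keep])); jj <- c(jj, unname(cb[keep]))
    rb <- row_index[b]; ca <- col_index[a]
    keep <- same & !is.na(rb) & !is.na(ca)
    ii <- c(ii, unname(rb[keep])); jj <- c(jj, unname(ca[keep]))
  }

  # bigram targets: locate adjacent member occurrences, then take contexts
  # beyond either end of the two-token span
  bi_rows <- vocab$rows[vocab$is_bigram]
  if (length(bi_rows) > 0L) {
    n <- nrow(dt)
    first <- tok[-n]; second <- tok[-1L]
    adjacent <- sid[-n] == sid[-1L]
    key <- paste(first, second)
    hit <- adjacent & key %in% bi_rows
    pos1 <- which(hit)                       # stream position of first member
    if (length(pos1) > 0L) {
      rbi <- row_index[key[pos1]]
      for (d in seq_len(half_window)) {
        # left contexts: d tokens before the first member
        p <- pos1 - d
        ok <- p >= 1L & sid[pmax(p, 1L)] == sid[pos1]
        cj <- col_index[tok[pmax(p, 1L)]]
        keep <- ok & !is.na(cj)
        ii <- c(ii, unname(rbi[keep])); jj <- c(jj, unname(cj[keep]))
        # right contexts: d tokens after the second member
        p <- pos1 + 1L + d
        ok <- p <= n & sid[pmin(p, n)] == sid[pos1]
        cj <- col_index[tok[pmin(p, n)]]
        keep <- ok & !is.na(cj)
        ii <- c(ii, unname(rbi[keep])); jj <- c(jj, unname(cj[keep]))
      }
    }
  }

  counts <- Matrix::sparseMatrix(
    i = ii, j = jj, x = rep.int(1L, length(ii)),
    dims = c(length(vocab$rows), length(cols)),
    dimnames = list(vocab$rows, cols)
  )
  structure(list(counts = counts, vocab = vocab),
            class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf("cooccurrence_matrix: %d x %d, %d nonzero cells, total count %d\n",
              nrow(x$counts), ncol(x$counts),
              Matrix::nnzero(x$counts), as.integer(sum(x$counts))))
  invisible(x)
}

#' Positive pointwise mutual information weighting
#'
#' Re-weights a raw co-occurrence count matrix cell-wise as
#' \code{max(0, log(p(a,b) / (p(a) p(b))))} where \code{p(a,b)} is the cell
#' probability and \code{p(a)}, \code{p(b)} are the row and column marginal
#' probabilities of the same matrix. Natural logarithm; cells with zero count
#' stay zero.
#'
#' @param counts a \code{cooccurrence_matrix} or a non-negative matrix.
#' @return a sparse non-negative matrix of the same shape and dimnames.
#' @export
ppmi <- function(counts) {
  m <- if (inherits(counts, "cooccurrence_matrix")) counts$counts else counts
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                   "TsparseMatrix")
  total <- sum(m@x)
  if (total <= 0) stop("degenerate input: all-zero count matrix")
  rs <- Matrix::rowSums(m)
  cs <- Matrix::colSums(m)
  i <- m@i + 1L
  j <- m@j + 1L
  val <- log(m@x) + log(total) - log(rs[i]) - log(cs[j])
  keep <- val > 0
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = val[keep],
                       dims = dim(m), dimnames = dimnames(m))
}
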