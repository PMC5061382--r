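#' Reduce a weighted co-occurrence matrix to a semantic space
#'
#' Factorizes the (PPMI-weighted) matrix as \code{W H} with both factors
#' non-negative and returns the row factor \code{W}: one \code{d}-dimensional
#' non-negative vector per vocabulary row. The factorization uses seeded
#' multiplicative updates on the Frobenius objective, so repeated runs with the
#' same seed give identical spaces.
#'
#' @param weighted non-negative matrix (dense or sparse) with row names.
#' @param d target dimensionality (1 <= d <= min(dim(weighted))).
#' @param seed integer seed for the factorization initialization.
#' @param tol relative-objective-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return an object of class \code{semantic_space}: fields \code{vectors}
#'   (|rows| x d matrix with row names), \code{d}, \code{is_bigram}, and
#'   \code{provenance} (method, d, seed, tolerance, iterations, achieved
#'   relative reconstruction error).
#' @export
reduce_dimensions <- function(weighted, d, seed, tol = 1e-4, max_iter = 500L) {
  x <- as.matrix(weighted)
  if (is.null(rownames(x))) {
    rownames(x) <- paste0("row", seq_len(nrow(x)))
  }
  fit <- nmf_factorize(x, d = d, seed = seed, tol = tol, max_iter = max_iter)
  vectors <- fit$w
  rownames(vectors) <- rownames(x)
  semantic_space(
    vectors,
    provenance = list(weighting = "ppmi", method = "nmf-multiplicative",
                      d = d, seed = as.integer(seed), tol = tol,
                      iterations = fit$iterations,
                      relative_error = fit$relative_error)
  )
}

#' Construct a semantic space from a vector matrix
#'
#' @param vectors numeric matrix, one row per target, with row names; bigram
#'   targets are identified by a space in the row name.
#' @param provenance optional list describing how the vectors were obtained.
#' @return an object of class \code{semantic_space}.
#' @export
semantic_space <- function(vectors, provenance = list()) {
  vectors <- as.matrix(vectors)
  stopifnot(!is.null(rownames(vectors)), !anyDuplicated(rownames(vectors)))
  structure(
    list(vectors = vectors,
         d = ncol(vectors),
         is_bigram = is_bigram_target(rownames(vectors)),
         provenance = provenance),
    class = "semantic_space"
  )
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("semantic_space: %d targets (%d bigram) x %d dimensions\n",
              nrow(x$vectors), sum(x$is_bigram), x$d))
  if (length(x$provenance)) {
    cat(sprintf("  method %s, seed %s, rel. reconstruction error %.4g\n",
                x$provenance$method %||% "?",
                as.character(x$provenance$seed %||% "?"),
                x$provenance$relative_error %||% NA_real_))
  }
  invisible(x)
}

#' Look up a target vector
#'
#' @param space a \code{semantic_space}.
#' @param target a single lemma, a space-joined bigram key, or a two-element
#'   character vector (modifier, head).
#' @return the numeric vector, or \code{NULL} if the target has no row.
#' @export
space_vector <- function(space, target) {
  stopifnot(inherits(space, "semantic_space"))
  key <- if (length(target) == 2L) bigram_key(target[1L], target[2L]) else target
  i <- match(key, rownames(space$vectors))
  if (is.na(i)) return(NULL)
  space$vectors[i, ]
}

#' Cosine similarity
#'
#' \code{dot(a, b) / (||a|| ||b||)}. For non-negative vectors the result lies
#' in [0, 1].
#'
#' @param a,b numeric vectors of equal length, neither all-zero.
#' @return cosine similarity in [-1, 1].
#' @export
cosine <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("undefined similarity: zero-norm vector")
  }
  sum(a * b) / (na * nb)
}

# cosines of v against every row of a matrix; rows with zero norm get NA
row_cosines <- function(mat, v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("undefined similarity: zero-norm query vector")
  norms <- sqrt(rowSums(mat^2))
  out <- as.numeric(mat %*% v) / (norms * nv)
  out[norms == 0] <- NA_real_
  out
}

#' Nearest neighbours in a semantic space
#'
#' Returns the \code{k} single-lemma rows with the highest cosine similarity
#' to \code{v}, in decreasing order; ties are broken by row order. Bigram
#' training rows are never eligible as neighbours.
#'
#' @param space a \code{semantic_space}.
#' @param v query vector of length \code{space$d}.
#' @param k number of neighbours.
#' @param exclude character vector of row targets to exclude.
#' @return data.frame with columns \code{target} and \code{cosine}.
#' @export
nearest_neighbours <- function(space, v, k, exclude = character(0)) {
  stopifnot(inherits(space, "semantic_space"), length(v) == space$d, k >= 1)
  eligible <- !space$is_bigram & !(rownames(space$vectors) %in% exclude)
  idx <- which(eligible)
  if (k > length(idx)) {
    stop(sprintf("k = %d exceeds the %d eligible rows", k, length(idx)))
  }
  cs <- row_cosines(space$vectors[idx, , drop = FALSE], v)
  cs[is.na(cs)] <- -Inf
  ord <- order(-cs, seq_along(cs), method = "radix")[seq_len(k)]
  data.frame(target = rownames(space$vectors)[idx[ord]],
             cosine = cs[ord],
             stringsAsFactors = FALSE)
}

#' Export / import a semantic space as delimited text
#'
#' The space is written as a tab-separated matrix (row names in the first
#' column) with a JSON-free sidecar \code{<path>.provenance.dcf} recording the
#' provenance fields.
#'
#' @param space a \code{semantic_space}.
#' @param path output file path.
#' @return \code{path} invisibly (\code{export_space}); a
#'   \code{semantic_space} (\code{import_space}).
#' @export
export_space <- function(space, path) {
  stopifnot(inherits(space, "semantic_space"))
  utils::write.table(space$vectors, path, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  prov <- space$provenance
  if (length(prov)) {
    write.dcf(data.frame(lapply(prov, as.character),
                         stringsAsFactors = FALSE),
              paste0(path, ".provenance.dcf"))
  }
  invisible(path)
}

#' @rdname export_space
#' @export
import_space <- function(path) {
  tab <- utils::read.table(path, sep = "\t", quote = "", header = FALSE,
                           row.names = 1, check.names = FALSE,
                           stringsAsFactors = FALSE)
  prov <- list()
  side <- paste0(path, ".provenance.dcf")
  if (file.exists(side)) {
    dcf <- read.dcf(side)
    prov <- as.list(dcf[1, ])
    for (f in c("d", "seed", "iterations")) {
      if (!is.null(prov[[f]])) prov[[f]] <- as.integer(prov[[f]])
    }
    for (f in c("tol", "relative_error")) {
      if (!is.null(prov[[f]])) prov[[f]] <- as.numeric(prov[[f]])
    }
  }
  semantic_space(as.matrix(tab), provenance = prov)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
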