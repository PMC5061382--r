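#' Adjacent-bigram frequencies of a corpus
#'
#' Counts every within-sentence occurrence of two adjacent tokens as one
#' ordered bigram token.
#'
#' @param corpus a \code{tokenized_corpus}.
#' @return data.table with columns \code{modifier}, \code{head}, \code{freq}.
#' @export
corpus_bigram_counts <- function(corpus) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  lens <- vapply(corpus$sentences, length, integer(1))
  tok <- unlist(corpus$sentences, use.names = FALSE)
  sid <- rep.int(seq_along(lens), lens)
  n <- length(tok)
  if (n < 2L) {
    return(data.table(modifier = character(0), head = character(0),
                      freq = integer(0)))
  }
  keep <- sid[-n] == sid[-1L]
  dt <- data.table(modifier = tok[-n][keep], head = tok[-1L][keep])
  dt[, list(freq = .N), by = c("modifier", "head")]
}

#' Extract modifier training pairs
#'
#' Candidate pairs are adjacent within-sentence token bigrams whose first token
#' is one of the designated modifiers. Pairs attested fewer than
#' \code{min_pair_freq} times, and pairs belonging to the item set, are
#' dropped; modifiers left with fewer than \code{min_pairs_per_modifier}
#' distinct pairs are dropped entirely. If a \code{semantic_space} is supplied,
#' each surviving pair's observed phrase vector is looked up from its bigram
#' row (an error if the space lacks it).
#'
#' @param corpus a \code{tokenized_corpus}.
#' @param modifiers character vector of modifier lemmata.
#' @param item_pairs two-column matrix or data.frame of (modifier, head)
#'   pairs to exclude from training, or NULL.
#' @param min_pair_freq minimum corpus bigram frequency (default 20).
#' @param min_pairs_per_modifier minimum distinct surviving pairs per
#'   modifier (default 50).
#' @param space optional \code{semantic_space} holding bigram rows.
#' @return an object of class \code{training_set}: \code{pairs} (data.table
#'   with modifier, head, freq), \code{vectors} (list per modifier of matrices
#'   of observed phrase vectors, when a space was given), \code{thresholds},
#'   \code{dropped_modifiers}, \code{excluded_items}.
#' @export
extract_training_pairs <- function(corpus, modifiers, item_pairs = NULL,
                                   min_pair_freq = 20L,
                                   min_pairs_per_modifier = 50L,
                                   space = NULL) {
  stopifnot(length(corpus$sentences) > 0,
            min_pair_freq >= 1, min_pairs_per_modifier >= 1)
  modifiers <- tolower(as.character(modifiers))
  bg <- corpus_bigram_counts(corpus)
  cand <- bg[bg$modifier %in% modifiers & bg$freq >= min_pair_freq, ]

  excluded <- cand[0, ]
  if (!is.null(item_pairs) && NROW(item_pairs) > 0) {
    ip <- as.data.frame(item_pairs, stringsAsFactors = FALSE)
    item_keys <- bigram_key(tolower(ip[[1L]]), tolower(ip[[2L]]))
    in_items <- bigram_key(cand$modifier, cand$head) %in% item_keys
    excluded <- cand[in_items, ]
    cand <- cand[!in_items, ]
  }

  n_by_mod <- table(cand$modifier)
  keep_mods <- names(n_by_mod)[n_by_mod >= min_pairs_per_modifier]
  dropped <- setdiff(unique(c(modifiers, cand$modifier)), keep_mods)
  cand <- cand[cand$modifier %in% keep_mods, ]
  data.table::setorder(cand, modifier, head)

  vectors <- NULL
  if (!is.null(space) && nrow(cand) > 0) {
    keys <- bigram_key(cand$modifier, cand$head)
    miss <- setdiff(keys, rownames(space$vectors))
    if (length(miss)) {
      stop("space lacks bigram rows for surviving training pairs, e.g. ",
           paste(utils::head(miss, 3), collapse = ", "))
    }
    vectors <- lapply(split(keys, cand$modifier), function(k) {
      space$vectors[k, , drop = FALSE]
    })
  }

  structure(
    list(pairs = cand,
         vectors = vectors,
         thresholds = list(min_pair_freq = min_pair_freq,
                           min_pairs_per_modifier = min_pairs_per_modifier),
         dropped_modifiers = sort(dropped),
         excluded_items = excluded),
    class = "training_set"
  )
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf(
    "training_set: %d pairs over %d modifiers (>= %d occurrences, >= %d pairs/modifier); %d modifiers dropped\n",
    nrow(x$pairs), length(unique(x$pairs$modifier)),
    x$thresholds$min_pair_freq, x$thresholds$min_pairs_per_modifier,
    length(x$dropped_modifiers)))
  invisible(x)
}

# ridge solution for multi-response least squares P ~ X, returns coefficient
# matrix (ncol(X) x ncol(P)); lambda = "gcv" selects over a log grid
ridge_solve <- function(x, p, lambda) {
  xtx <- crossprod(x)
  xtp <- crossprod(x, p)
  solve(xtx + diag(lambda, ncol(x)), xtp)
}

ridge_gcv <- function(x, p, grid = 10^seq(-6, 2, by = 1)) {
  sv <- svd(x)
  d2 <- sv$d^2
  utp <- crossprod(sv$u, p)
  n <- nrow(x)
  scores <- vapply(grid, function(lam) {
    shrink <- d2 / (d2 + lam)               # hat-matrix eigenvalues
    fit <- sv$u %*% (shrink * utp)
    rss <- sum((p - fit)^2)
    edf <- sum(shrink)
    n * rss / (n - min(edf, n - 1e-8))^2
  }, numeric(1))
  grid[which.min(scores)]
}

#' Fit a modifier lexical function
#'
#' Estimates the \code{d x (d+1)} matrix \code{M} (a \code{d x d} transform
#' plus a \code{d x 1} intercept) minimizing the summed squared Euclidean norm
#' between observed phrase vectors and the composed vectors \code{M [h; 1]},
#' with an optional ridge penalty \code{lambda ||M||_F^2}, in closed form via
#' the regularized normal equations.
#'
#' @param heads n x d matrix of head vectors (or list of vectors).
#' @param phrases n x d matrix of observed phrase vectors.
#' @param lambda non-negative ridge penalty, or \code{"gcv"} to select it by
#'   generalized cross-validation over the grid 1e-6 ... 1e2.
#' @param intercept include the intercept column (default TRUE).
#' @param modifier optional modifier lemma stored with the fit.
#' @return an object of class \code{lexical_function}: \code{matrix}
#'   (d x (d+1), or d x d without intercept), \code{modifier},
#'   \code{diagnostics} (pair count, residual norm, lambda).
#' @export
fit_lexical_function <- function(heads, phrases, lambda = "gcv",
                                 intercept = TRUE, modifier = NA_character_) {
  h <- if (is.list(heads)) do.call(rbind, heads) else as.matrix(heads)
  p <- if (is.list(phrases)) do.call(rbind, phrases) else as.matrix(phrases)
  if (nrow(h) == 0) stop("no training pairs")
  if (nrow(h) != nrow(p) || ncol(h) != ncol(p)) {
    stop("head and phrase vector dimensions disagree")
  }
  x <- if (intercept) cbind(h, 1) else h
  if (identical(lambda, "gcv")) lambda <- ridge_gcv(x, p)
  stopifnot(is.numeric(lambda), lambda >= 0)
  coefs <- ridge_solve(x, p, lambda)        # ncol(x) x d
  m <- t(coefs)                             # d x (d [+1])
  resid <- p - x %*% coefs
  structure(
    list(matrix = m, modifier = modifier, intercept = intercept,
         diagnostics = list(n_pairs = nrow(h),
                            residual_norm = sqrt(sum(resid^2)),
                            lambda = lambda)),
    class = "lexical_function"
  )
}

#' Fit a full-additive composition model
#'
#' Estimates the shared \code{d x d} matrices \code{(A, B)} of the model
#' \code{c = A m + B h} by ridge-regularized least squares on the stacked
#' \code{[m; h]} design (no intercept).
#'
#' @param mods,heads,phrases n x d matrices (or lists of vectors) of modifier,
#'   head, and observed phrase vectors.
#' @param lambda non-negative ridge penalty or \code{"gcv"}.
#' @return an object of class \code{full_additive_model} with fields \code{A},
#'   \code{B}, \code{diagnostics}.
#' @export
fit_full_additive <- function(mods, heads, phrases, lambda = "gcv") {
  m <- if (is.list(mods)) do.call(rbind, mods) else as.matrix(mods)
  h <- if (is.list(heads)) do.call(rbind, heads) else as.matrix(heads)
  p <- if (is.list(phrases)) do.call(rbind, phrases) else as.matrix(phrases)
  if (nrow(m) == 0) stop("no training pairs")
  if (!all(dim(m) == dim(h)) || !all(dim(h) == dim(p))) {
    stop("modifier, head and phrase vector dimensions disagree")
  }
  d <- ncol(h)
  x <- cbind(m, h)
  if (identical(lambda, "gcv")) lambda <- ridge_gcv(x, p)
  coefs <- ridge_solve(x, p, lambda)        # 2d x d
  a <- t(coefs[seq_len(d), , drop = FALSE])
  b <- t(coefs[d + seq_len(d), , drop = FALSE])
  resid <- p - x %*% coefs
  structure(
    list(A = a, B = b,
         diagnostics = list(n_pairs = nrow(m),
                            residual_norm = sqrt(sum(resid^2)),
                            lambda = lambda)),
    class = "full_additive_model"
  )
}

#' Composition model
#'
#' Bundles a composition method with its parameters: \code{"additive"} and
#' \code{"multiplicative"} are parameterless; \code{"full_additive"} carries a
#' \code{full_additive_model}; \code{"lexical_function"} carries a named list
#' of per-modifier \code{lexical_function} fits.
#'
#' @param method one of \code{"additive"}, \code{"multiplicative"},
#'   \code{"full_additive"}, \code{"lexical_function"}.
#' @param parameters the fitted parameters required by the method.
#' @return an object of class \code{composition_model}.
#' @export
composition_model <- function(method = c("additive", "multiplicative",
                                         "full_additive", "lexical_function"),
                              parameters = NULL) {
  method <- match.arg(method)
  if (method == "full_additive" &&
      !inherits(parameters, "full_additive_model")) {
    stop("full_additive requires a full_additive_model")
  }
  if (method == "lexical_function" &&
      (!is.list(parameters) || is.null(names(parameters)))) {
    stop("lexical_function requires a named list of lexical_function fits")
  }
  if (method %in% c("additive", "multiplicative") && !is.null(parameters)) {
    stop(method, " takes no parameters")
  }
  structure(list(method = method, parameters = parameters),
            class = "composition_model")
}

#' @export
print.composition_model <- function(x, ...) {
  extra <- switch(x$method,
                  lexical_function = sprintf(" (%d modifiers)",
                                             length(x$parameters)),
                  "")
  cat(sprintf("composition_model: %s%s\n", x$method, extra))
  invisible(x)
}

#' Train per-modifier lexical functions from a training set
#'
#' @param training a \code{training_set} built with a space (observed vectors
#'   attached).
#' @param space the \code{semantic_space} providing head vectors.
#' @param lambda ridge penalty or \code{"gcv"} (selected per modifier).
#' @return a \code{composition_model} of method \code{"lexical_function"}.
#' @export
train_lexical_functions <- function(training, space, lambda = "gcv") {
  stopifnot(inherits(training, "training_set"),
            !is.null(training$vectors),
            inherits(space, "semantic_space"))
  mods <- names(training$vectors)
  fits <- lapply(mods, function(md) {
    sub <- training$pairs[training$pairs$modifier == md, ]
    hv <- lapply(sub$head, function(hh) space_vector(space, hh))
    ok <- !vapply(hv, is.null, logical(1))
    fit_lexical_function(do.call(rbind, hv[ok]),
                         training$vectors[[md]][ok, , drop = FALSE],
                         lambda = lambda, modifier = md)
  })
  names(fits) <- mods
  composition_model("lexical_function", fits)
}

#' Compose a compound vector
#'
#' Applies a composition model to a (modifier, head) pair: additive
#' \code{m + h}; multiplicative \code{m * h} elementwise; full additive
#' \code{A m + B h}; lexical function \code{M [h; 1]}.
#'
#' @param model a \code{composition_model}.
#' @param modifier,head lemmata.
#' @param space a \code{semantic_space}.
#' @return numeric vector of length \code{space$d}, or \code{NULL} with a
#'   \code{"ncplaus_uncomposable"} condition message if the modifier has no
#'   fitted lexical function (the item is excluded downstream).
#' @export
compose_compound <- function(model, modifier, head, space) {
  stopifnot(inherits(model, "composition_model"),
            inherits(space, "semantic_space"))
  h <- space_vector(space, head)
  if (is.null(h)) stop("head lemma has no space vector: ", head)
  switch(model$method,
    additive = {
      m <- space_vector(space, modifier)
      if (is.null(m)) stop("modifier lemma has no space vector: ", modifier)
      m + h
    },
    multiplicative = {
      m <- space_vector(space, modifier)
      if (is.null(m)) stop("modifier lemma has no space vector: ", modifier)
      m * h
    },
    full_additive = {
      m <- space_vector(space, modifier)
      if (is.null(m)) stop("modifier lemma has no space vector: ", modifier)
      as.numeric(model$parameters$A %*% m + model$parameters$B %*% h)
    },
    lexical_function = {
      lf <- model$parameters[[modifier]]
      if (is.null(lf)) return(NULL)         # uncomposable: untrained modifier
      hx <- if (lf$intercept) c(h, 1) else h
      as.numeric(lf$matrix %*% hx)
    })
}
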