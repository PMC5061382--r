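#' Additive model specification
#'
#' Describes a Gaussian additive model: linear covariate terms, single-variable
#' penalized smooths, tensor-product interaction smooths of variable pairs, and
#' random-intercept factors.
#'
#' @param response response column name.
#' @param linear character vector of linear term names.
#' @param smooth character vector of smooth term variables.
#' @param tensor list of two-element character vectors (variable pairs).
#' @param random character vector of grouping factor names fitted as penalized
#'   random intercepts.
#' @return an object of class \code{model_spec}.
#' @export
model_spec <- function(response, linear = character(0), smooth = character(0),
                       tensor = list(), random = character(0)) {
  tensor <- lapply(tensor, as.character)
  stopifnot(all(vapply(tensor, length, integer(1)) == 2L))
  labels <- c(linear,
              if (length(smooth)) paste0("s(", smooth, ")"),
              vapply(tensor, function(p) paste0("te(", p[1], ",", p[2], ")"),
                     character(1)))
  if (anyDuplicated(labels)) stop("duplicate terms in model specification")
  structure(list(response = response, linear = linear, smooth = smooth,
                 tensor = tensor, random = random),
            class = "model_spec")
}

spec_variables <- function(spec) {
  unique(c(spec$response, spec$linear, spec$smooth,
           unlist(spec$tensor), spec$random))
}

tensor_label <- function(pair) paste0("te(", pair[1], ",", pair[2], ")")

#' @export
print.model_spec <- function(x, ...) {
  terms <- c(x$linear,
             if (length(x$smooth)) paste0("s(", x$smooth, ")"),
             vapply(x$tensor, tensor_label, character(1)),
             if (length(x$random)) paste0("re(", x$random, ")"))
  cat(sprintf("model_spec: %s ~ %s\n", x$response,
              if (length(terms)) paste(terms, collapse = " + ") else "1"))
  invisible(x)
}

spec_formula <- function(spec, k_main = 5L, k_tensor = 5L) {
  rhs <- c(
    spec$linear,
    if (length(spec$smooth)) sprintf("s(%s, k = %d)", spec$smooth, k_main),
    vapply(spec$tensor, function(p) {
      sprintf("te(%s, %s, k = c(%d, %d))", p[1], p[2], k_tensor, k_tensor)
    }, character(1)),
    if (length(spec$random)) sprintf("s(%s, bs = \"re\")", spec$random)
  )
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a Gaussian additive model
#'
#' Fits the model described by a \code{model_spec} with \code{mgcv::gam}:
#' penalized regression splines for smooth terms, tensor-product smooths for
#' interactions, and penalized group intercepts (\code{bs = "re"}) for random
#' factors. Rows with missing values on any used variable are dropped.
#'
#' @param table data.frame holding all spec variables.
#' @param spec a \code{model_spec}.
#' @param method smoothing-parameter selection criterion: \code{"REML"}
#'   (default) or \code{"ML"} (used by the selection procedures, whose
#'   likelihood-ratio comparisons require marginal likelihoods).
#' @param k_main basis dimension of single-variable smooths.
#' @param k_tensor per-margin basis dimension of tensor smooths.
#' @return an object of class \code{nc_gam} wrapping the \code{gam} fit with
#'   the spec, the rows used, log-likelihood, effective degrees of freedom,
#'   AIC and deviance explained.
#' @export
fit_gam <- function(table, spec, method = "REML", k_main = 5L, k_tensor = 5L) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- spec_variables(spec)
  missing_vars <- setdiff(vars, names(table))
  if (length(missing_vars)) {
    stop("table lacks variables: ", paste(missing_vars, collapse = ", "))
  }
  dat <- table[stats::complete.cases(table[, vars, drop = FALSE]), ,
               drop = FALSE]
  n_smooth_terms <- length(spec$smooth) + length(spec$tensor)
  if (nrow(dat) < max(10L * n_smooth_terms, 10L)) {
    stop(sprintf("estimation error: %d usable rows is too few for %d smooth term(s)",
                 nrow(dat), n_smooth_terms))
  }
  for (f in spec$random) dat[[f]] <- factor(dat[[f]])
  fml <- spec_formula(spec, k_main = k_main, k_tensor = k_tensor)
  # bam gives the same penalized fits at a fraction of the cost on larger
  # tables; plain gam is kept for small ones where bam's chunking buys
  # nothing, and is the fallback where bam's side-constraint handling cannot
  # set the model up (e.g. two tensor smooths sharing a margin)
  fit <- tryCatch({
    if (nrow(dat) >= 500L) {
      tryCatch(mgcv::bam(fml, data = dat, method = method),
               error = function(e) mgcv::gam(fml, data = dat, method = method))
    } else {
      mgcv::gam(fml, data = dat, method = method)
    }
  }, error = function(e) {
    stop("estimation error for ", deparse(fml), ": ", conditionMessage(e))
  })
  ll <- stats::logLik(fit)
  sm <- summary(fit)
  structure(
    list(fit = fit, spec = spec, method = method,
         k_main = k_main, k_tensor = k_tensor,
         data = dat, n_used = nrow(dat),
         loglik = as.numeric(ll), loglik_df = attr(ll, "df"),
         n_coef = length(stats::coef(fit)),
         aic = stats::AIC(fit), dev_expl = sm$dev.expl,
         p_table = sm$p.table, s_table = sm$s.table),
    class = "nc_gam"
  )
}

#' @export
print.nc_gam <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  n = %d, method = %s, AIC = %.2f, deviance explained = %.3f\n",
              x$n_used, x$method, x$aic, x$dev_expl))
  invisible(x)
}

#' Term-level report of a fitted additive model
#'
#' Mirrors the usual two-block presentation: linear coefficients with
#' estimate, SE, t and p; smooth/tensor terms with estimated df, residual df,
#' F and p.
#'
#' @param model an \code{nc_gam}.
#' @return list with data.frames \code{linear} and \code{smooth}.
#' @export
term_report <- function(model) {
  stopifnot(inherits(model, "nc_gam"))
  lin <- as.data.frame(model$p_table)
  names(lin) <- c("estimate", "se", "t", "p")
  smo <- as.data.frame(model$s_table)
  if (nrow(smo)) names(smo) <- c("edf", "ref_df", "F", "p")
  list(linear = lin, smooth = smo)
}

# p-values of the testable terms (linear terms except the intercept; smooth
# and tensor terms except the random-intercept smooths)
term_pvalues <- function(model) {
  lin <- model$p_table
  lp <- lin[rownames(lin) != "(Intercept)", 4]
  names(lp) <- rownames(lin)[rownames(lin) != "(Intercept)"]
  sp <- numeric(0)
  if (!is.null(model$s_table) && nrow(model$s_table)) {
    lab <- rownames(model$s_table)
    re_lab <- paste0("s(", model$spec$random, ")")
    keep <- !(lab %in% re_lab)
    sp <- model$s_table[keep, 4]
    names(sp) <- lab[keep]
  }
  c(lp, sp)
}

#' Likelihood-ratio test between nested additive models
#'
#' Twice the log-likelihood difference, referred to a chi-squared
#' distribution. Two reference degrees of freedom are available:
#' \code{"edf"} uses the difference in effective degrees of freedom of the
#' two fits (floored at 0.5 to keep the reference distribution proper when
#' penalization shrinks the added term to near-zero complexity) — an
#' approximation that is mildly anti-conservative for penalized additions;
#' \code{"coef"} uses the difference in coefficient counts (the full basis
#' dimension of the added terms), an upper bound that makes the test
#' conservative and is what the stepwise selection uses to control spurious
#' inclusion. Both models should be fitted with \code{method = "ML"}.
#'
#' @param null_model,alt_model \code{nc_gam} fits, \code{null_model} nested in
#'   \code{alt_model}.
#' @param df_method \code{"edf"} (default) or \code{"coef"}.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
lrt_gam <- function(null_model, alt_model, df_method = c("edf", "coef")) {
  df_method <- match.arg(df_method)
  stat <- 2 * (alt_model$loglik - null_model$loglik)
  stat <- max(stat, 0)
  df <- if (df_method == "coef") {
    max(alt_model$n_coef - null_model$n_coef, 1)
  } else {
    max(alt_model$loglik_df - null_model$loglik_df, 0.5)
  }
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# spec editing helpers -------------------------------------------------------

spec_add_smooth <- function(spec, var) {
  model_spec(spec$response, spec$linear, c(spec$smooth, var), spec$tensor,
             spec$random)
}

spec_add_tensor <- function(spec, pair, absorb = TRUE) {
  smooth <- spec$smooth
  linear <- spec$linear
  if (absorb) {
    smooth <- setdiff(smooth, pair)   # tensor smooths subsume their mains
    linear <- setdiff(linear, pair)
  }
  model_spec(spec$response, linear, smooth, c(spec$tensor, list(pair)),
             spec$random)
}

spec_drop_linear <- function(spec, var) {
  model_spec(spec$response, setdiff(spec$linear, var), spec$smooth,
             spec$tensor, spec$random)
}

included_measures <- function(spec, measures) {
  intersect(measures, c(spec$smooth, unlist(spec$tensor), spec$linear))
}

# baseline -------------------------------------------------------------------

#' Identify the baseline covariate model
#'
#' Starts from fixed linear effects for every candidate covariate plus random
#' intercepts for the grouping factors, after first screening out candidates
#' whose absolute correlation with an already-retained candidate exceeds
#' \code{cor_threshold}. Linear terms are then pruned iteratively: at each
#' pass the least significant term with Wald p >= alpha is removed and the
#' model refitted. The pruned model is counter-checked with likelihood-ratio
#' tests: a dropped covariate that still significantly improves the model is
#' re-admitted (and, to keep the two criteria from cycling, is thereafter
#' exempt from Wald pruning — the LRT overrides the Wald screen), and the
#' kept terms are verified to significantly worsen the model on removal.
#' Random effects are always retained.
#'
#' @param table data.frame with the response, covariates and grouping factors.
#' @param candidates character vector of candidate covariate names.
#' @param response response column name (default \code{"rating"}).
#' @param random grouping factors (default \code{c("modifier", "head")}).
#' @param alpha significance level (default 0.05).
#' @param cor_threshold collinearity screen threshold (default 0.6).
#' @return list with \code{model} (an \code{nc_gam}) and \code{trace} (a list
#'   recording the screen, every pruning step, and the counter-check LRTs).
#' @export
build_baseline <- function(table, candidates, response = "rating",
                           random = c("modifier", "head"),
                           alpha = 0.05, cor_threshold = 0.6) {
  stopifnot(all(candidates %in% names(table)))

  # collinearity screen (greedy, in candidate order)
  cc <- stats::complete.cases(table[, candidates, drop = FALSE])
  cors <- stats::cor(table[cc, candidates, drop = FALSE])
  kept <- character(0)
  screened <- list()
  for (v in candidates) {
    r <- if (length(kept)) max(abs(cors[v, kept])) else 0
    if (r > cor_threshold) {
      screened[[v]] <- list(covariate = v, max_abs_cor = r,
                            against = kept[which.max(abs(cors[v, kept]))])
    } else {
      kept <- c(kept, v)
    }
  }

  trace <- list(screened_out = screened, pruning = list(), counter_check = NULL)
  current <- kept
  dropped <- names(screened)
  protected <- character(0)   # LRT-readmitted terms are safe from re-pruning

  repeat {
    # Wald pruning loop
    repeat {
      spec <- model_spec(response, linear = current, random = random)
      fit <- fit_gam(table, spec, method = "ML")
      pv <- term_pvalues(fit)
      pv <- pv[names(pv) %in% setdiff(current, protected)]
      pv[is.na(pv)] <- 1      # rank-deficient terms are never significant
      if (!length(pv) || max(pv) < alpha) break
      worst <- names(pv)[which.max(pv)]
      trace$pruning[[length(trace$pruning) + 1L]] <-
        list(action = "drop", term = worst, wald_p = unname(max(pv)))
      dropped <- c(dropped, worst)
      current <- setdiff(current, worst)
    }

    # LRT counter-check: can any dropped covariate still improve the model?
    readd <- NULL
    checks <- list()
    for (v in setdiff(candidates, current)) {
      alt <- fit_gam(table, model_spec(response, linear = c(current, v),
                                       random = random), method = "ML")
      lrt <- lrt_gam(fit, alt, df_method = "coef")
      checks[[v]] <- list(term = v, lrt_p = lrt$p, aic = alt$aic)
      if (lrt$p < alpha && (is.null(readd) || alt$aic < readd$aic)) {
        readd <- list(term = v, aic = alt$aic, lrt_p = lrt$p)
      }
    }
    trace$counter_check <- checks
    if (is.null(readd)) break
    trace$pruning[[length(trace$pruning) + 1L]] <-
      list(action = "re-add", term = readd$term, lrt_p = readd$lrt_p)
    current <- c(current, readd$term)
    protected <- c(protected, readd$term)
    dropped <- setdiff(dropped, readd$term)
  }

  # verify kept terms: removal must significantly worsen the model
  removal <- list()
  for (v in current) {
    red <- fit_gam(table, model_spec(response, linear = setdiff(current, v),
                                     random = random), method = "ML")
    lrt <- lrt_gam(red, fit)
    removal[[v]] <- list(term = v, lrt_p = lrt$p)
  }
  trace$removal_check <- removal
  trace$retained <- current

  list(model = fit, trace = trace)
}

# stepwise selection ---------------------------------------------------------

candidate_spec <- function(spec, cand) {
  if (cand$type == "smooth") spec_add_smooth(spec, cand$var)
  else spec_add_tensor(spec, cand$pair, absorb = TRUE)
}

candidate_label <- function(cand) {
  if (cand$type == "smooth") paste0("s(", cand$var, ")")
  else tensor_label(cand$pair)
}

#' Stepwise selection of plausibility-measure terms
#'
#' Starting from the baseline model, repeatedly fits one candidate extension
#' per not-yet-included term and accepts, among the candidates whose
#' likelihood-ratio test against the current model is significant at
#' \code{alpha} and whose AIC improves on it, the one with the lowest AIC.
#' In the first phase the candidate set contains penalized smooth main
#' effects of the measures not yet in the model plus tensor-product
#' interactions among included measures; when a tensor interaction is
#' accepted, the main-effect smooths of its two variables are absorbed into
#' it. Once no such candidate is significant, a second phase offers
#' tensor-product interactions of each included measure with the pair
#' frequency covariate. All comparison fits use marginal likelihood
#' (\code{method = "ML"}), and the acceptance LRTs use the conservative
#' coefficient-count reference df (see \code{\link{lrt_gam}}) so that testing
#' several null candidates per step does not inflate spurious inclusion.
#'
#' @param table analysis data.frame.
#' @param baseline an \code{nc_gam} (typically from
#'   \code{\link{build_baseline}}).
#' @param measures character vector of measure column names.
#' @param pair_freq_var pair-frequency covariate used in phase two (default
#'   \code{"log_pair_freq"}).
#' @param alpha significance level (default 0.05).
#' @param max_steps safety cap on accepted steps.
#' @return list with \code{model} (final \code{nc_gam}) and \code{trace}
#'   (class \code{stepwise_trace}: one entry per step with every candidate's
#'   LRT statistic, p and AIC, and the accepted term or stop).
#' @export
stepwise_select <- function(table, baseline, measures,
                            pair_freq_var = "log_pair_freq",
                            alpha = 0.05, max_steps = 20L) {
  stopifnot(inherits(baseline, "nc_gam"))
  current <- baseline
  steps <- list()

  gen_candidates <- function(spec, phase) {
    inc <- included_measures(spec, measures)
    cands <- list()
    if (phase == 1L) {
      for (m in setdiff(measures, inc)) {
        cands[[length(cands) + 1L]] <- list(type = "smooth", var = m)
      }
      if (length(inc) >= 2L) {
        existing <- vapply(spec$tensor, tensor_label, character(1))
        pairs <- utils::combn(inc, 2L, simplify = FALSE)
        for (p in pairs) {
          if (!(tensor_label(p) %in% existing) &&
              !(tensor_label(rev(p)) %in% existing)) {
            cands[[length(cands) + 1L]] <- list(type = "tensor", pair = p)
          }
        }
      }
    } else {
      existing <- vapply(spec$tensor, tensor_label, character(1))
      for (m in inc) {
        p <- c(m, pair_freq_var)
        if (!(tensor_label(p) %in% existing)) {
          cands[[length(cands) + 1L]] <- list(type = "tensor", pair = p)
        }
      }
    }
    cands
  }

  for (phase in 1:2) {
    repeat {
      if (length(steps) >= max_steps) break
      cands <- gen_candidates(current$spec, phase)
      if (!length(cands)) break
      rec <- list(phase = phase, candidates = list(), accepted = NULL)
      best <- NULL
      for (cand in cands) {
        spec_c <- candidate_spec(current$spec, cand)
        fit_c <- tryCatch(fit_gam(table, spec_c, method = "ML",
                                  k_main = current$k_main,
                                  k_tensor = current$k_tensor),
                          error = function(e) NULL)
        if (is.null(fit_c)) next
        lrt <- lrt_gam(current, fit_c, df_method = "coef")
        rec$candidates[[candidate_label(cand)]] <-
          list(term = candidate_label(cand), statistic = lrt$statistic,
               df = lrt$df, p = lrt$p, aic = fit_c$aic)
        if (lrt$p < alpha && fit_c$aic < current$aic &&
            (is.null(best) || fit_c$aic < best$fit$aic)) {
          best <- list(cand = cand, fit = fit_c, lrt = lrt)
        }
      }
      if (is.null(best)) {
        rec$accepted <- NA_character_
        steps[[length(steps) + 1L]] <- rec
        break
      }
      rec$accepted <- candidate_label(best$cand)
      rec$aic_before <- current$aic
      rec$aic_after <- best$fit$aic
      steps[[length(steps) + 1L]] <- rec
      current <- best$fit
    }
  }

  list(model = current,
       trace = structure(steps, class = "stepwise_trace"))
}

#' @export
print.stepwise_trace <- function(x, ...) {
  for (i in seq_along(x)) {
    st <- x[[i]]
    acc <- if (is.na(st$accepted)) "stop (no significant candidate)"
           else sprintf("accepted %s (AIC %.2f -> %.2f)", st$accepted,
                        st$aic_before, st$aic_after)
    cat(sprintf("step %d [phase %d]: %d candidates; %s\n",
                i, st$phase, length(st$candidates), acc))
  }
  invisible(x)
}

#' Export tensor-interaction surfaces as delimited grids
#'
#' For each tensor term of a fitted model, evaluates the model's predictions
#' on a regular grid of the two interacting variables (all other covariates
#' held at their medians, factors at their first level) and writes one
#' tab-separated table per term — the numbers behind a heat-map plot.
#'
#' @param model a fitted \code{nc_gam}.
#' @param dir output directory.
#' @param n_grid grid points per axis (default 25).
#' @return (invisibly) named list of the grid data.frames written.
#' @export
export_tensor_grids <- function(model, dir, n_grid = 25L) {
  stopifnot(inherits(model, "nc_gam"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dat <- model$data
  out <- list()
  for (pair in model$spec$tensor) {
    g1 <- seq(min(dat[[pair[1]]]), max(dat[[pair[1]]]), length.out = n_grid)
    g2 <- seq(min(dat[[pair[2]]]), max(dat[[pair[2]]]), length.out = n_grid)
    grid <- expand.grid(g1, g2)
    names(grid) <- pair
    for (v in setdiff(spec_variables(model$spec),
                      c(model$spec$response, pair))) {
      grid[[v]] <- if (is.factor(dat[[v]]) || is.character(dat[[v]])) {
        factor(levels(factor(dat[[v]]))[1], levels(factor(dat[[v]])))
      } else {
        stats::median(dat[[v]])
      }
    }
    grid$predicted <- as.numeric(stats::predict(model$fit, newdata = grid))
    keep <- c(pair, "predicted")
    fname <- file.path(dir, paste0("surface_", pair[1], "_x_", pair[2],
                                   ".tsv"))
    utils::write.table(grid[, keep], fname, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out[[tensor_label(pair)]] <- grid[, keep]
  }
  invisible(out)
}

# model criticism ------------------------------------------------------------

refit_nc_gam <- function(model, table) {
  fit_gam(table, model$spec, method = model$method,
          k_main = model$k_main, k_tensor = model$k_tensor)
}

all_terms_significant <- function(model, alpha) {
  pv <- term_pvalues(model)
  length(pv) == 0L || all(pv < alpha)
}

# replace one tensor term by main-effect smooths plus a linear product
# interaction of the same two variables; returns spec and the product column
linearized_spec <- function(spec, pair) {
  prod_col <- paste0(pair[1], "_X_", pair[2])
  tensor <- spec$tensor[!vapply(spec$tensor, function(p) {
    identical(as.character(p), as.character(pair))
  }, logical(1))]
  smooth <- unique(c(spec$smooth, pair))
  list(spec = model_spec(spec$response, c(spec$linear, prod_col), smooth,
                         tensor, spec$random),
       prod_col = prod_col, pair = pair)
}

#' Post-fit model criticism
#'
#' Three checks of a final model: (1) an outlier refit, dropping rows whose
#' residual deviates more than \code{sd_threshold} standard deviations from
#' the model predictions and refitting the same specification; (2) a
#' linearity check per tensor term, comparing the tensor model against one
#' where that term is replaced by main-effect smooths plus a linear product
#' interaction; (3) a non-negative-proximity refit on the rows with
#' non-negative modifier and head proximity.
#'
#' @param table the analysis data.frame the model was fitted on.
#' @param final a fitted \code{nc_gam}.
#' @param alpha significance level for the term-significance flags.
#' @param sd_threshold residual SD multiple defining outliers (default 2.5).
#' @param min_rows smallest refit size allowed (default 50).
#' @param checks which blocks to run (default all three); restricting them
#'   skips the corresponding refits.
#' @return an object of class \code{criticism_report} with blocks
#'   \code{outliers}, \code{linearity}, \code{nonnegative} (NULL when not
#'   requested).
#' @export
criticize_model <- function(table, final, alpha = 0.05, sd_threshold = 2.5,
                            min_rows = 50L,
                            checks = c("outliers", "linearity",
                                       "nonnegative")) {
  stopifnot(inherits(final, "nc_gam"))
  checks <- match.arg(checks, several.ok = TRUE)
  dat <- final$data
  outliers <- NULL
  if ("outliers" %in% checks) {
    res <- stats::residuals(final$fit)
    keep <- abs(res) <= sd_threshold * stats::sd(res)
    if (sum(keep) < min_rows) {
      stop("criticism aborted: only ", sum(keep),
           " rows after outlier removal")
    }
    refit_out <- refit_nc_gam(final, dat[keep, , drop = FALSE])
    outliers <- list(
      n_removed = sum(!keep),
      all_terms_significant = all_terms_significant(refit_out, alpha),
      dev_expl_full = final$dev_expl,
      dev_expl_refit = refit_out$dev_expl
    )
  }

  linearity_check <- function(model, data) {
    out <- list()
    for (pair in model$spec$tensor) {
      lin <- linearized_spec(model$spec, pair)
      data2 <- data
      data2[[lin$prod_col]] <- data[[pair[1]]] * data[[pair[2]]]
      fit_lin <- fit_gam(data2, lin$spec, method = "ML",
                         k_main = model$k_main, k_tensor = model$k_tensor)
      fit_ten <- fit_gam(data2, model$spec, method = "ML",
                         k_main = model$k_main, k_tensor = model$k_tensor)
      lrt <- lrt_gam(fit_lin, fit_ten)
      out[[tensor_label(pair)]] <-
        list(term = tensor_label(pair), statistic = lrt$statistic,
             df = lrt$df, p = lrt$p)
    }
    out
  }
  linearity <- if ("linearity" %in% checks) linearity_check(final, dat)

  nonnegative <- NULL
  if ("nonnegative" %in% checks) {
    keep_nn <- rep(TRUE, nrow(dat))
    for (v in intersect(c("modifier_proximity", "head_proximity"),
                        names(dat))) {
      keep_nn <- keep_nn & dat[[v]] >= 0
    }
    if (sum(keep_nn) < min_rows) {
      stop("criticism aborted: only ", sum(keep_nn),
           " rows with non-negative proximities")
    }
    refit_nn <- refit_nc_gam(final, dat[keep_nn, , drop = FALSE])
    nonnegative <- list(
      n_removed = sum(!keep_nn),
      all_terms_significant = all_terms_significant(refit_nn, alpha),
      dev_expl_refit = refit_nn$dev_expl,
      linearity = linearity_check(refit_nn, dat[keep_nn, , drop = FALSE])
    )
  }

  structure(list(outliers = outliers, linearity = linearity,
                 nonnegative = nonnegative),
            class = "criticism_report")
}

#' @export
print.criticism_report <- function(x, ...) {
  cat("criticism_report\n")
  if (!is.null(x$outliers)) {
    cat(sprintf(" outlier refit: %d rows removed; all terms significant: %s; deviance explained %.3f -> %.3f\n",
                x$outliers$n_removed, x$outliers$all_terms_significant,
                x$outliers$dev_expl_full, x$outliers$dev_expl_refit))
  }
  for (l in x$linearity) {
    cat(sprintf(" tensor vs linear %s: LRT = %.2f (df %.2f), p = %.3g\n",
                l$term, l$statistic, l$df, l$p))
  }
  if (!is.null(x$nonnegative)) {
    cat(sprintf(" non-negative-proximity refit: %d rows removed; all terms significant: %s\n",
                x$nonnegative$n_removed, x$nonnegative$all_terms_significant))
  }
  invisible(x)
}
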