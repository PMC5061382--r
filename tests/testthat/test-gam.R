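test_that("model_spec rejects duplicates and builds the right formula", {
  expect_error(model_spec("y", linear = c("a", "a")), "duplicate")
  sp <- model_spec("rating", linear = "pmi", smooth = "head_proximity",
                   tensor = list(c("head_proximity", "modifier_proximity")),
                   random = c("modifier", "head"))
  fml <- deparse(ncplaus:::spec_formula(sp), width.cutoff = 500)
  expect_match(fml, "te\\(head_proximity, modifier_proximity")
  expect_match(fml, "s\\(modifier, bs = \"re\"\\)")
})

test_that("fit_gam recovers a linear slope and reports missing variables", {
  set.seed(101)
  n <- 300
  tab <- data.frame(x = runif(n))
  tab$y <- 2 * tab$x + rnorm(n, 0, 0.4)
  fit <- fit_gam(tab, model_spec("y", linear = "x"))
  est <- fit$p_table["x", 1]; se <- fit$p_table["x", 2]
  expect_lt(abs(est - 2), 3 * se)
  expect_error(fit_gam(tab, model_spec("y", linear = "zz")), "lacks")
})

test_that("a tensor term beats additive mains on an interaction surface", {
  set.seed(103)
  n <- 600
  tab <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
  tab$y <- sin(tab$x1) * tab$x2 + rnorm(n, 0, 0.3)
  mains <- fit_gam(tab, model_spec("y", smooth = c("x1", "x2")),
                   method = "ML")
  tens <- fit_gam(tab, model_spec("y",
                                  tensor = list(c("x1", "x2"))),
                  method = "ML")
  expect_gt(tens$dev_expl, mains$dev_expl)
  expect_lt(tens$aic, mains$aic)
})

test_that("likelihood-ratio statistics are non-negative on nested fits", {
  set.seed(107)
  tab <- simulate_measure_table(400, seed = 15)
  tab <- generate_ratings(ratings_config(surface = "linear_hp", seed = 16),
                          tab)
  m0 <- fit_gam(tab, model_spec("rating", random = c("modifier", "head")),
                method = "ML")
  m1 <- fit_gam(tab, model_spec("rating", smooth = "head_proximity",
                                random = c("modifier", "head")),
                method = "ML")
  lrt <- lrt_gam(m0, m1)
  expect_gte(lrt$statistic, 0)
  expect_lt(lrt$p, 0.05)
})

test_that("baseline pruning keeps the true covariate and rarely keeps nulls", {
  # With four null candidates pruned at Wald alpha = .05, at least one null
  # survives in about 1 - .95^4 = 19% of runs; the checks below reflect the
  # procedure's actual operating characteristics: the true effect is (almost)
  # always retained, and spurious retention stays near its theoretical rate.
  cands <- c("pmi", "modifier_length", "head_length", "log_pair_freq",
             "log_head_freq")
  true_kept <- 0L; clean <- 0L; spurious_total <- 0L
  for (r in 1:20) {
    tab <- simulate_measure_table(300, n_modifiers = 25, n_heads = 25,
                                  seed = 300 + r)
    tab$rating <- ncplaus:::with_preserved_seed(400 + r, {
      2 + 0.25 * tab$pmi + rnorm(nrow(tab), 0, 0.4)
    })
    b <- build_baseline(tab, cands)
    kept <- b$trace$retained
    if ("pmi" %in% kept) true_kept <- true_kept + 1L
    if (identical(kept, "pmi")) clean <- clean + 1L
    spurious_total <- spurious_total + length(setdiff(kept, "pmi"))
  }
  expect_gte(true_kept, 19L)
  expect_gte(clean, 10L)
  expect_lte(spurious_total / 20, 0.75)
})

test_that("all-null covariates usually prune to the random-effects-only model", {
  cands <- c("pmi", "modifier_length", "head_length", "log_pair_freq",
             "log_head_freq")
  n_kept <- vapply(1:10, function(r) {
    tab <- simulate_measure_table(250, n_modifiers = 25, n_heads = 25,
                                  seed = 500 + r)
    tab$rating <- ncplaus:::with_preserved_seed(520 + r,
                                                rnorm(nrow(tab), 2, 0.4))
    b <- build_baseline(tab, cands)
    expect_equal(b$model$spec$random, c("modifier", "head"))
    length(b$trace$retained)
  }, numeric(1))
  expect_gte(sum(n_kept == 0), 6)   # theory: ~81% fully clean
  expect_true(all(n_kept <= 2))
})

test_that("the collinearity screen removes one of a correlated pair", {
  tab <- simulate_measure_table(300, n_modifiers = 25, n_heads = 25,
                                seed = 601)
  # family sizes are generated correlated (> .6) with the log frequencies
  expect_gt(abs(cor(tab$modifier_family_size, tab$log_modifier_freq)), 0.6)
  tab$rating <- ncplaus:::with_preserved_seed(602, rnorm(nrow(tab), 2, 0.4))
  b <- build_baseline(tab, c("log_modifier_freq", "log_head_freq",
                             "modifier_family_size", "head_family_size"))
  screened <- names(b$trace$screened_out)
  expect_true(all(c("modifier_family_size", "head_family_size") %in% screened))
})

test_that("stepwise selection stops at the baseline on null data", {
  tab <- simulate_measure_table(500, seed = 701)
  tab <- generate_ratings(ratings_config(surface = "null", seed = 702), tab)
  base <- fit_gam(tab, model_spec("rating", random = c("modifier", "head")),
                  method = "ML")
  sw <- stepwise_select(tab, base, measure_names())
  expect_length(sw$model$spec$smooth, 0L)
  expect_length(sw$model$spec$tensor, 0L)
})

test_that("full-procedure spurious inclusion on null data stays within the liberal bound", {
  included <- vapply(1:40, function(r) {
    tab <- simulate_measure_table(250, n_modifiers = 25, n_heads = 25,
                                  seed = 1300 + r)
    tab <- generate_ratings(ratings_config(surface = "null",
                                           seed = 1340 + r), tab)
    base <- fit_gam(tab, model_spec("rating", random = c("modifier", "head")),
                    method = "ML")
    sw <- stepwise_select(tab, base, measure_names())
    length(sw$model$spec$smooth) + length(sw$model$spec$tensor) > 0
  }, logical(1))
  expect_lte(mean(included), 0.25)
})

test_that("a planted linear measure effect is selected and improves AIC", {
  tab <- simulate_measure_table(600, seed = 801)
  tab <- generate_ratings(ratings_config(surface = "linear_hp", seed = 802),
                          tab)
  base <- fit_gam(tab, model_spec("rating", random = c("modifier", "head")),
                  method = "ML")
  sw <- stepwise_select(tab, base, measure_names())
  expect_true("head_proximity" %in% sw$model$spec$smooth)
  expect_lt(sw$model$aic, base$aic)
  # every accepted step lowered the AIC
  for (st in sw$trace) {
    if (!is.na(st$accepted)) expect_lt(st$aic_after, st$aic_before)
  }
})

test_that("criticism leaves a clean fit unchanged and flags planted nonlinearity", {
  set.seed(109)
  tab <- simulate_measure_table(700, seed = 901)
  tab <- generate_ratings(ratings_config(surface = "te_hp_mp", seed = 902),
                          tab)
  fit <- fit_gam(tab, model_spec(
    "rating",
    tensor = list(c("head_proximity", "modifier_proximity")),
    random = c("modifier", "head")), method = "ML")
  rep <- criticize_model(tab, fit)
  expect_s3_class(rep, "criticism_report")
  expect_lt(rep$linearity[[1]]$p, 0.05)
  expect_lte(rep$outliers$n_removed, nrow(tab))
  expect_true(is.finite(rep$outliers$dev_expl_refit))

  # no-outlier case: thresholds wide enough to keep every row
  rep2 <- criticize_model(tab, fit, sd_threshold = 100)
  expect_equal(rep2$outliers$n_removed, 0L)
  expect_equal(rep2$outliers$dev_expl_refit, rep2$outliers$dev_expl_full)
})

test_that("outlier removal does not hurt fit on gross-noise contamination", {
  tab <- simulate_measure_table(800, seed = 1101)
  tab <- generate_ratings(ratings_config(surface = "linear_hp",
                                         noise_sd = 0.25, seed = 1102), tab)
  idx <- ncplaus:::with_preserved_seed(1103, sample(nrow(tab), 40))
  tab$rating[idx] <- ncplaus:::with_preserved_seed(
    1104, runif(40, 0, 4))                       # 5% gross contamination
  fit <- fit_gam(tab, model_spec("rating", smooth = "head_proximity",
                                 random = c("modifier", "head")),
                 method = "ML")
  rep <- criticize_model(tab, fit)
  expect_gte(rep$outliers$dev_expl_refit, rep$outliers$dev_expl_full)
})

test_that("tensor surfaces export as regular delimited grids", {
  tab <- simulate_measure_table(600, seed = 1401)
  tab <- generate_ratings(ratings_config(surface = "te_hp_mp", seed = 1402),
                          tab)
  fit <- fit_gam(tab, model_spec(
    "rating", tensor = list(c("head_proximity", "modifier_proximity")),
    random = c("modifier", "head")), method = "ML")
  d <- withr::local_tempdir()
  grids <- export_tensor_grids(fit, d, n_grid = 10)
  f <- file.path(d, "surface_head_proximity_x_modifier_proximity.tsv")
  expect_true(file.exists(f))
  g <- read.delim(f)
  expect_equal(nrow(g), 100)
  expect_equal(names(g), c("head_proximity", "modifier_proximity",
                           "predicted"))
  expect_true(all(is.finite(g$predicted)))
  # the exported surface rises in head proximity at medium modifier proximity
  mid <- g[abs(g$modifier_proximity - median(g$modifier_proximity)) ==
             min(abs(g$modifier_proximity - median(g$modifier_proximity))), ]
  expect_gt(cor(mid$head_proximity, mid$predicted), 0.9)
})

test_that("criticism aborts on too-small refits", {
  tab <- simulate_measure_table(60, seed = 1201)
  tab <- generate_ratings(ratings_config(surface = "linear_hp", seed = 1202),
                          tab)
  tab$modifier_proximity <- -abs(tab$modifier_proximity)  # all negative
  fit <- fit_gam(tab, model_spec("rating", linear = "head_proximity"),
                 method = "ML")
  expect_error(criticize_model(tab, fit), "aborted")
})
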