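MEASURE_COLUMNS <- c("head_proximity", "modifier_proximity",
                     "constituent_similarity", "neighbourhood_density",
                     "entropy")

COVARIATE_COLUMNS <- c("modifier_length", "head_length", "log_pair_freq",
                       "log_rev_pair_freq", "log_modifier_freq",
                       "log_head_freq", "pmi",
                       "modifier_family_size", "head_family_size")

#' Pipeline configuration
#'
#' Bundles every stage parameter with defaults matching the reference
#' settings: +-2-word window, 300 reduced dimensions, training filters of 20
#' pair occurrences and 50 pairs per modifier, neighbourhood size 20, and
#' alpha = 0.05.
#'
#' @param corpus_path,items_path,freq_path input files (ignored when
#'   \code{synthetic = TRUE}).
#' @param out_dir output directory.
#' @param synthetic generate corpus, items and ratings from the seeded
#'   synthetic model instead of reading files.
#' @param synthetic_corpus optional \code{corpus_config} overriding the
#'   default synthetic preset.
#' @param synthetic_ratings optional \code{ratings_config}.
#' @param dialect corpus file dialect.
#' @param n_content vocabulary size (top content lemmata).
#' @param half_window window half-width (default 2).
#' @param dims reduced dimensionality (default 300).
#' @param min_pair_freq,min_pairs_per_modifier training-set filters
#'   (defaults 20 and 50).
#' @param lambda ridge policy for the lexical functions (default "gcv").
#' @param k neighbourhood size (default 20).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for every stochastic stage.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(corpus_path = NULL, items_path = NULL,
                            freq_path = NULL, out_dir = "ncplaus_out",
                            synthetic = FALSE, synthetic_corpus = NULL,
                            synthetic_ratings = NULL,
                            dialect = "plain", n_content = 20000L,
                            half_window = 2L, dims = 300L,
                            min_pair_freq = 20L, min_pairs_per_modifier = 50L,
                            lambda = "gcv", k = 20L, alpha = 0.05,
                            seed = 1L) {
  # the full-corpus training filters exceed what the default synthetic corpus
  # can attest (.15 * 30000 / 6 = 750 compound tokens per modifier cannot
  # yield 50 pairs of frequency 20); the synthetic preset scales them down
  # unless explicitly overridden
  if (isTRUE(synthetic)) {
    if (missing(min_pair_freq)) min_pair_freq <- 10L
    if (missing(min_pairs_per_modifier)) min_pairs_per_modifier <- 10L
  }
  structure(as.list(environment()), class = "pipeline_config")
}

config_fingerprint <- function(config) {
  # fingerprint the analysis-relevant parameters, not the I/O paths
  keep <- setdiff(names(config),
                  c("corpus_path", "items_path", "freq_path", "out_dir"))
  cfg <- config[keep]
  txt <- paste(deparse(cfg[!vapply(cfg, is.function, logical(1))]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 0xFFFFFFF)
}

#' Run the full analysis pipeline
#'
#' Executes corpus reading (or synthesis), training-pair extraction, semantic
#' space construction (co-occurrence counting, PPMI, non-negative
#' factorization), lexical-function training, measure and covariate
#' computation, baseline-model identification, stepwise measure selection and
#' model criticism, writing every artefact plus a provenance log to
#' \code{out_dir}. Re-running with an identical configuration reproduces
#' identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return (invisibly) a list with the space, training set, composition
#'   model, item table, baseline, stepwise result and criticism report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("ncplaus pipeline, config fingerprint %s",
                         config_fingerprint(config)),
                 sprintf("seed: %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # stage: corpus + items
  ledger <- NULL
  if (isTRUE(config$synthetic)) {
    cc <- config$synthetic_corpus %||%
      corpus_config(seed = config$seed)
    gen <- stage("synthetic corpus", generate_corpus(cc))
    corpus <- gen$corpus
    ledger <- gen$ledger
    items <- ledger$item_pairs
    modifiers <- ledger$modifiers
  } else {
    if (is.null(config$corpus_path) || !file.exists(config$corpus_path)) {
      stop("input error: corpus file not found: ",
           config$corpus_path %||% "<missing>")
    }
    if (is.null(config$items_path) || !file.exists(config$items_path)) {
      stop("input error: items file not found: ",
           config$items_path %||% "<missing>")
    }
    corpus <- stage("read corpus",
                    read_corpus(config$corpus_path, config$dialect))
    items <- stage("read items", read_item_table(config$items_path))
    modifiers <- unique(items$modifier)
  }
  log_lines <- c(log_lines,
                 sprintf("corpus: %d sentences, %d tokens",
                         length(corpus$sentences), corpus$token_count),
                 sprintf("items: %d", nrow(items)))

  # stage: training-pair survivors (decides which bigram rows the space needs)
  pre_training <- stage("training filter", extract_training_pairs(
    corpus, modifiers, items[, c("modifier", "head")],
    config$min_pair_freq, config$min_pairs_per_modifier))
  training_bigrams <- lapply(seq_len(nrow(pre_training$pairs)), function(i) {
    c(pre_training$pairs$modifier[i], pre_training$pairs$head[i])
  })

  # stage: semantic space
  extra <- c(as.list(unique(c(modifiers, items$modifier, items$head))),
             training_bigrams)
  vocab <- stage("vocabulary",
                 build_vocabulary(corpus, config$n_content, extra))
  counts <- stage("co-occurrence counting",
                  count_cooccurrences(corpus, vocab, config$half_window))
  weighted <- stage("ppmi", ppmi(counts))
  dims <- min(config$dims, nrow(weighted), ncol(weighted))
  space <- stage("dimension reduction",
                 reduce_dimensions(weighted, dims, seed = config$seed))
  export_space(space, file.path(config$out_dir, "space.tsv"))
  log_lines <- c(log_lines,
                 sprintf("space: %d rows x %d dims, rel. error %.4f",
                         nrow(space$vectors), space$d,
                         space$provenance$relative_error))

  # stage: composition model
  training <- stage("training vectors", extract_training_pairs(
    corpus, modifiers, items[, c("modifier", "head")],
    config$min_pair_freq, config$min_pairs_per_modifier, space = space))
  model <- stage("lexical functions",
                 train_lexical_functions(training, space,
                                         lambda = config$lambda))
  log_lines <- c(log_lines,
                 sprintf("lexical functions: %d modifiers trained, %d dropped",
                         length(model$parameters),
                         length(training$dropped_modifiers)))

  # stage: frequencies + item table
  freqs <- if (!is.null(config$freq_path)) {
    stage("frequency table", read_frequency_table(config$freq_path))
  } else {
    frequency_table(corpus)
  }
  table <- stage("item measures",
                 assemble_item_table(items, space, model, freqs,
                                     k = config$k))
  if (isTRUE(config$synthetic)) {
    rc <- config$synthetic_ratings %||% ratings_config(seed = config$seed)
    ok <- !table$excluded
    rated <- generate_ratings(rc, table[ok, , drop = FALSE])
    table$rating <- NA_real_
    table$rating[ok] <- rated$rating
  }
  utils::write.table(table, file.path(config$out_dir, "item_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage: analysis
  analysis_rows <- table[!table$excluded & !is.na(table$rating), ,
                         drop = FALSE]
  if (nrow(analysis_rows) < 30L) {
    stop(sprintf(
      "pipeline stage 'analysis' failed: only %d usable items (need >= 30); enlarge the item set or relax the training filters",
      nrow(analysis_rows)), call. = FALSE)
  }
  baseline <- stage("baseline model",
                    build_baseline(analysis_rows, COVARIATE_COLUMNS,
                                   alpha = config$alpha))
  stepwise <- stage("stepwise selection",
                    stepwise_select(analysis_rows, baseline$model,
                                    MEASURE_COLUMNS, alpha = config$alpha))
  if (length(stepwise$model$spec$tensor)) {
    export_tensor_grids(stepwise$model, file.path(config$out_dir, "surfaces"))
  }
  criticism <- tryCatch(
    criticize_model(analysis_rows, stepwise$model, alpha = config$alpha),
    error = function(e) {
      log_lines <<- c(log_lines, paste("criticism skipped:",
                                       conditionMessage(e)))
      NULL
    })

  report <- c(
    utils::capture.output(print(stepwise$model)),
    "", "Linear coefficients:",
    utils::capture.output(print(term_report(stepwise$model)$linear)),
    "", "Smooth / tensor terms:",
    utils::capture.output(print(term_report(stepwise$model)$smooth)),
    "", "Stepwise trace:",
    utils::capture.output(print(stepwise$trace)),
    "",
    if (!is.null(criticism)) utils::capture.output(print(criticism))
  )
  writeLines(report, file.path(config$out_dir, "report.txt"))
  writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))

  invisible(list(space = space, training = training, model = model,
                 table = table, baseline = baseline, stepwise = stepwise,
                 criticism = criticism, ledger = ledger))
}
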