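#' Run the full classification pipeline on one train/test split
#'
#' Executes the whole method end to end: a stratified 70/30 split, per-gene
#' Z-scoring fitted on the training partition only, improved cuckoo-search
#' gene selection (fitness = validation accuracy on an inner stratified
#' split of the training data), weighted-CNN training on the selected
#' genes, and evaluation of the held-out test partition (confusion-matrix
#' metrics plus ROC/AUC). `selection = FALSE` runs the identical pipeline
#' without the gene-selection stage, the "without gene selection" ablation.
#' All stage seeds derive deterministically from `seed`, so the run is
#' bit-reproducible.
#'
#' @param df An expression table (see [expression_table()]).
#' @param cs A [cs_params()] configuration (its `seed` is overridden by the
#'   derived stage seed).
#' @param wcnn A [wcnn_config()] (likewise).
#' @param split_fraction Training fraction of the outer stratified split.
#' @param inner_fraction Training fraction of the inner split feeding the
#'   selection fitness.
#' @param selection Run the gene-selection stage? Default `TRUE`.
#' @param evaluator Fitness classifier for the selection stage.
#' @param seed Global seed.
#' @return A list of class `geneflight_run`: `report` (one-row metrics
#'   tibble), `roc` (a `roc_curve`), `selection` (an `icso_result` or
#'   `NULL`), `model`, `predictions`, `n_train`, `n_test`, `seed`, and a
#'   `log` tibble of the stages run.
#' @export
run_pipeline <- function(df, cs = cs_params(), wcnn = wcnn_config(),
                         split_fraction = 0.7, inner_fraction = 0.7,
                         selection = TRUE,
                         evaluator = nearest_centroid_evaluator, seed = 1) {
  df <- validate_expression_table(df)
  split <- stratified_split(df, split_fraction, derive_seed(seed, "split"))
  fit_eval_pipeline(
    train = split$train, test = split$test, cs = cs, wcnn = wcnn,
    inner_fraction = inner_fraction, selection = selection,
    evaluator = evaluator, seed = seed
  )
}

# Shared by the holdout and cross-validation drivers: normalize on train,
# select, train the CNN, evaluate on test.
fit_eval_pipeline <- function(train, test, cs, wcnn, inner_fraction,
                              selection, evaluator, seed) {
  log <- list()
  note <- function(stage, detail) {
    log[[length(log) + 1L]] <<- tibble(
      stage = stage, detail = detail, time = format(Sys.time(), "%H:%M:%S")
    )
  }

  stats <- zscore_fit(train)
  train_z <- zscore_apply(train, stats)
  test_z <- zscore_apply(test, stats)
  note("normalize", sprintf("z-score fitted on %d training samples", nrow(train)))

  sel <- NULL
  if (selection) {
    cs$seed <- derive_seed(seed, "icso")
    inner <- stratified_split(train_z, inner_fraction, derive_seed(seed, "inner"))
    sel <- icso_select(inner$train, inner$test, cs, evaluator)
    keep <- c("sample_id", "label", sel$selected_gene_ids)
    train_z <- train_z[keep]
    test_z <- test_z[keep]
    note("select", sprintf(
      "icso seed %d: %d of %d genes, fitness %.4f",
      cs$seed, length(sel$selected_gene_ids), length(sel$best_mask),
      sel$best_fitness
    ))
  } else {
    note("select", "skipped (without gene selection)")
  }

  wcnn$seed <- derive_seed(seed, "wcnn")
  model <- wcnn_train(train_z, wcnn)
  note("train", sprintf(
    "wcnn seed %d: %d epochs, final train accuracy %.4f",
    wcnn$seed, wcnn$epochs, tail(model$history$accuracy, 1)
  ))

  preds <- predict(model, test_z)
  y <- label_codes(test_z)
  yhat <- as.integer(preds$.pred_class) - 1L
  report <- metrics_report(y, yhat)
  pos_col <- paste0(".pred_", model$label_levels[2])
  roc <- roc_points(preds[[pos_col]], y)
  note("evaluate", sprintf(
    "test n = %d, accuracy %.2f%%, AUC %.4f",
    nrow(test_z), report$accuracy, roc_auc(roc)
  ))

  structure(
    list(
      report = report, roc = roc, selection = sel, model = model,
      predictions = preds, n_train = nrow(train), n_test = nrow(test),
      seed = seed, log = dplyr::bind_rows(log)
    ),
    class = "geneflight_run"
  )
}

#' @export
print.geneflight_run <- function(x, ...) {
  cat(
    "geneflight pipeline run\n",
    sprintf("  train/test: %d/%d samples\n", x$n_train, x$n_test),
    if (!is.null(x$selection)) {
      sprintf(
        "  selected genes: %d (fitness %.4f)\n",
        length(x$selection$selected_gene_ids), x$selection$best_fitness
      )
    } else "  gene selection: skipped\n",
    sprintf(
      "  test accuracy %.2f%%, precision %.2f%%, recall %.2f%%, F %.2f%%, AUC %.3f\n",
      x$report$accuracy, x$report$precision, x$report$recall,
      x$report$f_measure, roc_auc(x$roc)
    ),
    sep = ""
  )
  invisible(x)
}

#' Cross-validated pipeline
#'
#' Runs the pipeline of [run_pipeline()] inside stratified k-fold
#' cross-validation: for every fold, the remaining folds form the training
#' partition (normalization, selection and CNN training all refit from
#' scratch) and the fold is evaluated. Returns per-fold metric reports and
#' their [aggregate_folds()] average, the "average performance" row of a
#' five-fold results table.
#'
#' @inheritParams run_pipeline
#' @param k Number of folds; default 5.
#' @return A list of class `geneflight_cv`: `folds` (k-row metrics tibble
#'   with a `fold` column), `average` (one-row tibble), `k`, `seed`.
#' @export
crossval_pipeline <- function(df, k = 5, cs = cs_params(), wcnn = wcnn_config(),
                              inner_fraction = 0.7, selection = TRUE,
                              evaluator = nearest_centroid_evaluator, seed = 1) {
  df <- validate_expression_table(df)
  folds <- stratified_kfold(df, k, derive_seed(seed, "kfold"))
  per_fold <- purrr::map(seq_len(k), function(f) {
    in_fold <- folds$fold == f
    run <- fit_eval_pipeline(
      train = df[!in_fold, , drop = FALSE], test = df[in_fold, , drop = FALSE],
      cs = cs, wcnn = wcnn, inner_fraction = inner_fraction,
      selection = selection, evaluator = evaluator,
      seed = derive_seed(seed, paste0("fold", f))
    )
    dplyr::mutate(run$report, fold = f, .before = 1)
  })
  fold_reports <- dplyr::bind_rows(per_fold)
  structure(
    list(
      folds = fold_reports,
      average = aggregate_folds(fold_reports),
      k = k, seed = seed
    ),
    class = "geneflight_cv"
  )
}

#' @export
print.geneflight_cv <- function(x, ...) {
  cat(sprintf("geneflight %d-fold cross-validation\n", x$k))
  print(as.data.frame(x$folds), row.names = FALSE)
  cat("average:\n")
  print(as.data.frame(x$average), row.names = FALSE)
  invisible(x)
}

#' Read a pipeline run configuration
#'
#' Reads a YAML or JSON run configuration with blocks mirroring the
#' constructor arguments: top-level `matrix`, `labels`, `orientation`,
#' `delim`, `out_dir`, `split_fraction`, `inner_fraction`, `selection`,
#' `cv_k`, `seed`, plus `cs` and `wcnn` blocks whose keys mirror
#' [cs_params()] and [wcnn_config()]. Every block is validated by its
#' constructor before any computation.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of validated configuration values.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is needed for YAML configs; use JSON instead.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- list(
    matrix = raw$matrix, labels = raw$labels,
    orientation = raw$orientation %||% "genes_as_rows",
    delim = raw$delim,
    out_dir = raw$out_dir %||% ".",
    split_fraction = raw$split_fraction %||% 0.7,
    inner_fraction = raw$inner_fraction %||% 0.7,
    selection = raw$selection %||% TRUE,
    cv_k = raw$cv_k,
    seed = raw$seed %||% 1
  )
  cfg$cs <- do.call(cs_params, as.list(raw$cs %||% list()))
  cfg$wcnn <- do.call(wcnn_config, as.list(raw$wcnn %||% list()))
  cfg
}

#' Execute a configured run and write its artifacts
#'
#' Loads the dataset named by the configuration, runs [run_pipeline()] (or
#' [crossval_pipeline()] when `cv = TRUE`), and writes the metrics report
#' (TSV + JSON), the selection result, the serialized model, predictions,
#' and a per-stage log into `out_dir`.
#'
#' @param config A list from [read_run_config()], or a path to one.
#' @param cv Run the k-fold protocol instead of the single split.
#' @param selection Override the config's selection flag (e.g. `FALSE` for
#'   the "without gene selection" ablation).
#' @param seed Optional seed override.
#' @return The `geneflight_run` or `geneflight_cv` object, invisibly.
#' @export
run_from_config <- function(config, cv = FALSE, selection = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  df <- read_expression(
    config$matrix,
    orientation = config$orientation, labels = config$labels,
    delim = config$delim
  )
  selection <- selection %||% config$selection
  seed <- seed %||% config$seed
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (cv) {
    res <- crossval_pipeline(
      df,
      k = config$cv_k %||% 5, cs = config$cs, wcnn = config$wcnn,
      inner_fraction = config$inner_fraction, selection = selection,
      seed = seed
    )
    write_metrics_report(
      dplyr::bind_rows(res$folds, dplyr::mutate(res$average, fold = NA_integer_)),
      file.path(config$out_dir, "cv_metrics"),
      run_labels = c(paste0("fold_", seq_len(res$k)), "average")
    )
  } else {
    res <- run_pipeline(
      df,
      cs = config$cs, wcnn = config$wcnn,
      split_fraction = config$split_fraction,
      inner_fraction = config$inner_fraction,
      selection = selection, seed = seed
    )
    lbl <- if (selection) "with_selection" else "without_selection"
    write_metrics_report(res$report, file.path(config$out_dir, "metrics"),
      run_labels = lbl
    )
    readr::write_tsv(res$roc, file.path(config$out_dir, "roc_points.tsv"))
    readr::write_tsv(res$predictions, file.path(config$out_dir, "predictions.tsv"))
    if (!is.null(res$selection)) {
      write_selection(res$selection, config$out_dir)
    }
    write_wcnn(res$model, file.path(config$out_dir, "wcnn_model.json"))
    readr::write_tsv(res$log, file.path(config$out_dir, "run_log.tsv"))
  }
  invisible(res)
}
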