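#' Confusion counts
#'
#' Tallies true/false positives and negatives of binary predictions against
#' reference labels, with an explicit positive class (by default class code
#' 1, the tumor class under the package's lexicographic label coding).
#'
#' @param labels,predictions Vectors of class codes in `{0, 1}` (logical or
#'   two-level factors are accepted), equal length.
#' @param positive_class The class counted as positive, 0 or 1.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
#' @export
confusion <- function(labels, predictions, positive_class = 1) {
  labels <- as_code01(labels)
  predictions <- as_code01(predictions)
  if (length(labels) != length(predictions) || length(labels) < 1L) {
    abort("`labels` and `predictions` must have equal length >= 1.")
  }
  pos <- labels == positive_class
  hit <- labels == predictions
  tibble(
    tp = sum(pos & hit), fp = sum(!pos & !hit),
    tn = sum(!pos & hit), fn = sum(pos & !hit)
  )
}

as_code01 <- function(x) {
  if (is.factor(x)) {
    return(as.integer(x) - 1L)
  }
  if (is.logical(x)) {
    return(as.integer(x))
  }
  x <- as.integer(x)
  if (!all(x %in% c(0L, 1L))) abort("class codes must be 0 or 1.")
  x
}

undefined_metric <- function(what) {
  abort(sprintf("%s is undefined (zero denominator).", what),
    class = "geneflight_undefined_metric"
  )
}

#' Confusion-matrix percentage metrics
#'
#' Standard classifier metrics on a 0-100 percent scale.
#' `accuracy_pct()` defaults to overall correctness
#' `100 (TP+TN) / (TP+FP+TN+FN)`; `variant = "paper_literal"` instead
#' computes `100 TP / (TP+FP)`, a positive-predictive-value form that some
#' sources print as "accuracy" (it coincides with precision) — kept for
#' transparency, not as the default. `error_rate_pct()` is the complement
#' `100 - accuracy`. Undefined metrics (zero denominators) raise a
#' `geneflight_undefined_metric` condition; report builders convert that to
#' `NA`.
#'
#' @param counts A one-row tibble/list from [confusion()].
#' @param variant Accuracy definition, `"standard"` (default) or
#'   `"paper_literal"`.
#' @param precision,recall Percentages, for [f_measure_pct()].
#' @param accuracy Accuracy percentage, for [error_rate_pct()].
#' @return A percentage in `[0, 100]`.
#' @export
accuracy_pct <- function(counts, variant = c("standard", "paper_literal")) {
  variant <- match.arg(variant)
  if (variant == "standard") {
    n <- counts$tp + counts$fp + counts$tn + counts$fn
    if (n == 0) undefined_metric("accuracy")
    100 * (counts$tp + counts$tn) / n
  } else {
    if (counts$tp + counts$fp == 0) undefined_metric("accuracy (paper_literal)")
    100 * counts$tp / (counts$tp + counts$fp)
  }
}

#' @rdname accuracy_pct
#' @export
precision_pct <- function(counts) {
  if (counts$tp + counts$fp == 0) undefined_metric("precision")
  100 * counts$tp / (counts$tp + counts$fp)
}

#' @rdname accuracy_pct
#' @export
recall_pct <- function(counts) {
  if (counts$tp + counts$fn == 0) undefined_metric("recall")
  100 * counts$tp / (counts$tp + counts$fn)
}

#' @rdname accuracy_pct
#' @export
f_measure_pct <- function(precision, recall) {
  if (precision + recall == 0) {
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' @rdname accuracy_pct
#' @export
error_rate_pct <- function(accuracy) {
  check_number(accuracy, "accuracy", 0, 100)
  100 - accuracy
}

#' Full metrics report for one evaluation
#'
#' Computes accuracy, precision, recall, F-measure and error rate (all in
#' percent) from labels and predictions. Metrics whose denominator is zero
#' are reported as `NA`. Values are kept at full precision; rounding to the
#' two decimals used in printed tables happens only in
#' [write_metrics_report()].
#'
#' @inheritParams confusion
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f_measure`, `error_rate`.
#' @export
metrics_report <- function(labels, predictions, positive_class = 1) {
  cts <- confusion(labels, predictions, positive_class)
  safe <- function(expr) {
    tryCatch(expr, geneflight_undefined_metric = function(e) NA_real_)
  }
  acc <- safe(accuracy_pct(cts))
  prec <- safe(precision_pct(cts))
  rec <- safe(recall_pct(cts))
  f <- if (is.na(prec) || is.na(rec)) NA_real_ else f_measure_pct(prec, rec)
  tibble(
    accuracy = acc, precision = prec, recall = rec, f_measure = f,
    error_rate = if (is.na(acc)) NA_real_ else error_rate_pct(acc)
  )
}

#' Average per-fold metric reports
#'
#' Arithmetic mean of each metric column across cross-validation folds, the
#' "average performance" row of a k-fold results table.
#'
#' @param reports A tibble of per-fold [metrics_report()] rows.
#' @return A one-row tibble with the same columns.
#' @export
aggregate_folds <- function(reports) {
  if (!is.data.frame(reports) || nrow(reports) < 1L) {
    abort("`reports` must contain at least one fold report.")
  }
  dplyr::summarise(reports, dplyr::across(
    dplyr::all_of(intersect(
      c("accuracy", "precision", "recall", "f_measure", "error_rate"),
      names(reports)
    )),
    mean
  ))
}

#' Serialize metric reports
#'
#' Writes a metrics table both as JSON (full precision) and as a TSV laid
#' out like the printed comparison tables — metrics as rows, one column per
#' report — with values rounded half-up to two decimals.
#'
#' @param reports A tibble of [metrics_report()] rows.
#' @param path Output path without extension (writes `<path>.json` and
#'   `<path>.tsv`).
#' @param run_labels Optional column labels (default `fold_1`, ... or
#'   `run`).
#' @return Invisibly, the two paths written.
#' @export
write_metrics_report <- function(reports, path, run_labels = NULL) {
  metric_cols <- intersect(
    c("accuracy", "precision", "recall", "f_measure", "error_rate"),
    names(reports)
  )
  run_labels <- run_labels %||%
    if (nrow(reports) == 1L) "run" else paste0("fold_", seq_len(nrow(reports)))
  json_path <- paste0(path, ".json")
  tsv_path <- paste0(path, ".tsv")
  jsonlite::write_json(reports, json_path, auto_unbox = TRUE, digits = NA)
  round2 <- function(x) {
    ifelse(is.na(x), NA_real_, floor(x * 100 + 0.5) / 100)
  }
  wide <- tibble(metric = metric_cols)
  for (i in seq_len(nrow(reports))) {
    wide[[run_labels[i]]] <- round2(unlist(reports[i, metric_cols]))
  }
  readr::write_tsv(wide, tsv_path)
  invisible(c(json_path, tsv_path))
}

#' ROC curve and AUC
#'
#' Sweeps a descending sequence of score thresholds (the unique scores with
#' a sentinel above the maximum) and records the false- and true-positive
#' rates, from (0, 0) to (1, 1). The area under the curve is computed by
#' the trapezoid rule, which on such a step curve equals the Mann-Whitney
#' U-statistic probability that a random positive scores above a random
#' negative (ties counting half).
#'
#' @param scores Numeric scores for the positive class.
#' @param labels Class codes in `{0, 1}` (1 = positive), both classes
#'   present.
#' @return A tibble of class `roc_curve` with columns `threshold`, `fpr`,
#'   `tpr`, and the AUC in `attr(, "auc")` (also via [roc_auc()]).
#' @export
roc_points <- function(scores, labels) {
  labels <- as_code01(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  if (length(unique(labels)) < 2L) {
    abort("ROC needs both classes present.")
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  tpr <- vapply(thresholds, function(th) sum(scores >= th & labels == 1L), numeric(1)) / n_pos
  fpr <- vapply(thresholds, function(th) sum(scores >= th & labels == 0L), numeric(1)) / n_neg
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(
    tibble(threshold = thresholds, fpr = fpr, tpr = tpr),
    auc = auc, class = c("roc_curve", class(tibble()))
  )
}

#' @rdname roc_points
#' @param x An object with an AUC: a `roc_curve` from [roc_points()].
#' @export
roc_auc <- function(x) attr(x, "auc")

#' Plot a ROC curve
#'
#' @param object A `roc_curve` from [roc_points()].
#' @param ... Unused.
#' @return A ggplot object with the chance diagonal for reference.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_step() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1.05)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    )
}
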