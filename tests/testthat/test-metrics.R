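test_that("confusion counts match a direct per-element tally", {
  c1 <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(as.list(c1), list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  c2 <- confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(c2$tp + c2$tn, 0L)
  expect_equal(c2$fp, 2L)

  set.seed(12)
  for (i in 1:10) {
    y <- sample(0:1, 30, TRUE)
    p <- sample(0:1, 30, TRUE)
    cts <- confusion(y, p, positive_class = 1)
    tally <- table(factor(y, 0:1), factor(p, 0:1))
    expect_equal(cts$tp, tally["1", "1"])
    expect_equal(cts$tn, tally["0", "0"])
    expect_equal(cts$fp, tally["0", "1"])
    expect_equal(cts$fn, tally["1", "0"])
    expect_equal(cts$tp + cts$fp + cts$tn + cts$fn, 30L)
  }
  expect_error(confusion(c(0, 1), c(1)), "equal length")
})

test_that("percentage metrics follow their defining ratios", {
  cts <- tibble::tibble(tp = 9, fp = 1, tn = 8, fn = 2)
  expect_equal(precision_pct(cts), 90)
  expect_equal(recall_pct(cts), 9 / 11 * 100)
  expect_equal(accuracy_pct(cts), 85)
  expect_equal(accuracy_pct(cts, "paper_literal"), 90)
  expect_equal(error_rate_pct(accuracy_pct(cts)), 15)
  expect_equal(error_rate_pct(100), 0)
  expect_equal(error_rate_pct(0), 100)

  expect_equal(recall_pct(tibble::tibble(tp = 8, fp = 0, tn = 0, fn = 2)), 80)
  expect_equal(precision_pct(tibble::tibble(tp = 3, fp = 0, tn = 1, fn = 0)), 100)
  expect_equal(precision_pct(tibble::tibble(tp = 0, fp = 4, tn = 1, fn = 0)), 0)

  zero <- tibble::tibble(tp = 0, fp = 0, tn = 5, fn = 3)
  expect_error(precision_pct(zero), "undefined")
  expect_error(recall_pct(tibble::tibble(tp = 0, fp = 2, tn = 5, fn = 0)), "undefined")

  # accuracy + default error rate is exactly 100
  set.seed(1)
  for (i in 1:20) {
    y <- sample(0:1, 25, TRUE)
    p <- sample(0:1, 25, TRUE)
    a <- accuracy_pct(confusion(y, p))
    expect_identical(a + error_rate_pct(a), 100)
  }
})

test_that("F-measure reproduces published two-decimal values", {
  round2 <- function(x) floor(x * 100 + 0.5) / 100
  expect_equal(round2(f_measure_pct(90.28, 89.18)), 89.73)
  expect_equal(round2(f_measure_pct(86.20, 85.51)), 85.85)
  # the third published table's F (92.45) was rounded from unrounded inputs;
  # the harmonic mean of its printed precision/recall is 92.4567, which
  # agrees with the published value at its printed precision
  expect_equal(round2(f_measure_pct(93.01, 91.91)), 92.46)
  expect_lt(abs(f_measure_pct(93.01, 91.91) - 92.45), 0.01)
  # harmonic-mean fixed point and betweenness
  expect_equal(f_measure_pct(73.5, 73.5), 73.5)
  set.seed(2)
  for (i in 1:50) {
    pr <- runif(2, 1, 100)
    f <- f_measure_pct(pr[1], pr[2])
    expect_gte(f, min(pr))
    expect_lte(f, max(pr))
  }
  expect_equal(f_measure_pct(0, 0), 0)
})

test_that("fold aggregation averages each metric and ignores order", {
  t1 <- tibble::tibble(
    accuracy = c(84.30, 85.14, 85.15, 85.25, 85.28),
    precision = c(86.20, 86.22, 86.41, 86.46, 86.48),
    recall = c(85.51, 85.53, 85.66, 85.58, 85.59),
    f_measure = c(85.85, 85.96, 85.98, 85.97, 85.98)
  )
  avg <- aggregate_folds(t1)
  round2 <- function(x) floor(x * 100 + 0.5) / 100
  expect_equal(round2(avg$accuracy), 85.02)
  expect_equal(round2(avg$precision), 86.35)
  expect_equal(round2(avg$recall), 85.57)
  expect_equal(round2(avg$f_measure), 85.95)

  expect_equal(aggregate_folds(t1[sample(5), ]), avg)
  same <- t1[c(2, 2, 2), ]
  expect_equal(aggregate_folds(same), t1[2, ])
  two <- tibble::tibble(accuracy = c(0, 100))
  expect_equal(aggregate_folds(two)$accuracy, 50)
  expect_error(aggregate_folds(t1[0, ]), "at least one")
})

test_that("metric reports handle degenerate predictions as NA", {
  rep <- metrics_report(c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_true(is.na(rep$precision)) # no positive predictions
  expect_equal(rep$accuracy, 50)
  expect_equal(rep$recall, 0)

  dir <- withr::local_tempdir()
  paths <- write_metrics_report(rep, file.path(dir, "m"))
  tsv <- readr::read_tsv(paths[2], show_col_types = FALSE)
  expect_equal(tsv$metric, c("accuracy", "precision", "recall", "f_measure", "error_rate"))
  expect_equal(tsv$run[1], 50)
})

test_that("ROC points sweep thresholds and AUC equals the U-statistic", {
  perfect <- roc_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(roc_auc(perfect), 1)
  expect_equal(perfect$fpr[1], 0)
  expect_equal(tail(perfect$tpr, 1), 1)

  worst <- roc_points(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(roc_auc(worst), 0)

  set.seed(33)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- round(rnorm(n), sample(c(1, 6), 1)) # sometimes forces ties
    rc <- roc_points(scores, labels)
    expect_true(all(diff(rc$fpr) >= 0))
    expect_true(all(diff(rc$tpr) >= 0))
    expect_equal(roc_auc(rc), auc_mann_whitney(scores, labels), tolerance = 1e-12)
  }

  expect_error(roc_points(c(0.3, 0.4), c(1, 1)), "both classes")
  expect_s3_class(autoplot(perfect), "ggplot")
})
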