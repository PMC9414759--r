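test_that("regression errors match hand arithmetic and loop oracles", {
  ps <- prediction_set(y = c(9, 9), yhat = c(10, 8))
  expect_equal(mae(ps), 1.0)
  expect_equal(mse(ps), 1.0)
  expect_equal(mae(prediction_set(1:5, 1:5)), 0)
  expect_equal(mse(prediction_set(4, 7)), 9)

  mae_oracle <- function(y, yh) {
    s <- 0
    for (i in seq_along(y)) s <- s + abs(yh[i] - y[i])
    s / length(y)
  }
  mse_oracle <- function(y, yh) {
    s <- 0
    for (i in seq_along(y)) s <- s + (yh[i] - y[i])^2
    s / length(y)
  }
  set.seed(81)
  for (k in 1:20) {
    n <- sample(1:50, 1)
    y <- stats::runif(n, 0, 16)
    yh <- y + stats::rnorm(n, 0, 2)
    ps <- prediction_set(y, yh)
    expect_equal(mae(ps), mae_oracle(y, yh), tolerance = 1e-12)
    expect_equal(mse(ps), mse_oracle(y, yh), tolerance = 1e-12)
  }

  expect_error(prediction_set(numeric(0), numeric(0)), "at least one")
  expect_error(prediction_set(1:3, 1:2), "lengths differ")
  expect_error(prediction_set(c(1, NA), c(1, 2)), "finite")
})

test_that("risk classification thresholds at 9 g inclusive", {
  expect_equal(classify_risk(9.0), "FFH")
  expect_equal(classify_risk(8.99), "non-FFH")
  expect_equal(classify_risk(15.2), "FFH")
  expect_equal(classify_risk(c(2, 9, 12), threshold_g = 9),
               c("non-FFH", "FFH", "FFH"))
  expect_equal(classify_risk(9.5, threshold_g = 10), "non-FFH")
  expect_error(classify_risk(NA), "finite")
})

test_that("confusion metrics match an independent counting oracle", {
  # constructed set: 15 TP, 9 FN among positives
  y <- c(rep(10, 24), rep(2, 10))
  yhat <- c(rep(12, 15), rep(3, 9), rep(1, 10))
  cm <- confusion_metrics(prediction_set(y, yhat))
  expect_equal(cm$counts, list(TP = 15L, FP = 0L, TN = 10L, FN = 9L))
  expect_equal(cm$sensitivity_pct, 62.5)
  expect_equal(cm$specificity_pct, 100)
  expect_equal(cm$accuracy_pct, 100 * 25 / 34)

  oracle <- function(y, yh, thr) {
    tp <- fp <- tn <- fn <- 0L
    for (i in seq_along(y)) {
      if (y[i] >= thr && yh[i] >= thr) tp <- tp + 1L
      if (y[i] < thr && yh[i] >= thr) fp <- fp + 1L
      if (y[i] < thr && yh[i] < thr) tn <- tn + 1L
      if (y[i] >= thr && yh[i] < thr) fn <- fn + 1L
    }
    list(TP = tp, FP = fp, TN = tn, FN = fn)
  }
  set.seed(82)
  for (k in 1:50) {
    n <- sample(2:60, 1)
    y <- stats::runif(n, 0, 16)
    yh <- y + stats::rnorm(n, 0, 3)
    thr <- stats::runif(1, 4, 12)
    cm <- confusion_metrics(prediction_set(y, yh), thr)
    cnt <- oracle(y, yh, thr)
    expect_identical(cm$counts, cnt)
    expect_equal(sum(unlist(cm$counts)), n)
    if (cnt$TP + cnt$FN > 0) {
      expect_equal(cm$sensitivity_pct, 100 * cnt$TP / (cnt$TP + cnt$FN))
    }
    if (cnt$TN + cnt$FP > 0) {
      expect_equal(cm$specificity_pct, 100 * cnt$TN / (cnt$TN + cnt$FP))
    }
    expect_equal(cm$accuracy_pct, 100 * (cnt$TP + cnt$TN) / n)
  }
})

test_that("zero-denominator metrics are flagged undefined, not zeroed", {
  all_neg <- prediction_set(y = c(1, 2, 3), yhat = c(1, 2, 3))
  cm <- confusion_metrics(all_neg)
  expect_equal(cm$accuracy_pct, 100)
  expect_true(is.na(cm$sensitivity_pct))
  expect_equal(cm$undefined, "sensitivity")

  all_pos <- prediction_set(y = c(10, 11), yhat = c(12, 13))
  cm2 <- confusion_metrics(all_pos)
  expect_true(is.na(cm2$specificity_pct))
  expect_equal(cm2$undefined, "specificity")
})

test_that("metrics are permutation invariant and monotone in the threshold", {
  set.seed(83)
  y <- stats::runif(40, 0, 16)
  yh <- y + stats::rnorm(40, 0, 2)
  ps <- prediction_set(y, yh)
  perm <- sample(40)
  ps_p <- prediction_set(y[perm], yh[perm])
  expect_equal(mae(ps), mae(ps_p))
  expect_equal(mse(ps), mse(ps_p))
  expect_identical(confusion_metrics(ps)$counts, confusion_metrics(ps_p)$counts)

  pos_calls <- vapply(seq(2, 15, by = 0.5), function(thr) {
    cnt <- confusion_metrics(ps, thr)$counts
    cnt$TP + cnt$FP
  }, numeric(1))
  expect_true(all(diff(pos_calls) <= 0))
})

test_that("per-movement summaries use the n-1 standard deviation", {
  ps <- prediction_set(y = c(2, 4, 7), yhat = c(2.5, 3.5, 8),
                       movement_code = c("NF01", "NF01", "LF05"),
                       category = c("NF", "NF", "LF"))
  tab <- per_movement_summary(ps)
  nf <- tab[tab$movement_code == "NF01", ]
  expect_equal(nf$n, 2L)
  expect_equal(nf$true_mean, 3)
  expect_equal(nf$true_sd, sqrt(2), tolerance = 1e-12)
  lf <- tab[tab$movement_code == "LF05", ]
  expect_equal(lf$n, 1L)
  expect_true(is.na(lf$true_sd))      # single pair: spread not estimable
})

test_that("the report bundles metrics and enforces the MAE <= sqrt(MSE) invariant", {
  set.seed(84)
  for (k in 1:20) {
    y <- stats::runif(30, 0, 16)
    yh <- y + stats::rnorm(30, 0, 2)
    ps <- prediction_set(y, yh, movement_code = sample(c("NF01", "HF05"), 30,
                                                       replace = TRUE))
    rep <- evaluation_report(ps, model_label = "check")
    expect_lte(rep$mae_g, sqrt(rep$mse_g2) + 1e-12)
    expect_gte(rep$mse_g2, 0)
    expect_true(all(rep$per_movement$n >= 1))
  }

  ps <- prediction_set(c(2, 10), c(3, 11), movement_code = c("NF01", "HF05"),
                       category = c("NF", "HF"))
  rep <- evaluation_report(ps, model_label = "demo")
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, json, csv)
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$mae_g, 1)
  expect_equal(parsed$confusion$counts$TP, 1)
  expect_equal(nrow(utils::read.csv(csv)), 2L)
})
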