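test_that("configs enforce per-architecture layer counts and schedules", {
  c1 <- model_config("cnn1d", c(16, 16))
  expect_equal(c1$max_epochs, 200L)
  expect_equal(c1$patience, 100L)
  expect_equal(c1$batch_size, 1L)
  cl <- model_config("lstm", c(8, 16))
  expect_equal(cl$max_epochs, 50L)
  expect_equal(cl$patience, 10L)
  expect_silent(model_config("convlstm", c(16, 64, 64, 16)))
  expect_error(model_config("convlstm", c(16, 64)), "4 layer sizes")
  expect_error(model_config("cnn1d", c(16, 16, 16)), "2 layer sizes")
  expect_error(model_config("mlp", c(4, 4)))
})

test_that("every architecture maps a 50x8 window to one finite scalar", {
  set.seed(77)
  x <- matrix(stats::rnorm(400), 50, 8)
  for (arch in c("cnn1d", "cnn2d", "lstm", "convlstm")) {
    sizes <- if (arch == "convlstm") c(16, 16, 16, 16) else c(8, 16)
    m <- build_model(model_config(arch, sizes, seed = 2))
    out <- forward_sample(m, x)$yhat
    expect_length(out, 1L)
    expect_true(is.finite(out))
    expect_gt(count_params(m), 0L)
  }
})

test_that("analytic gradients agree with finite differences in all architectures", {
  set.seed(99)
  x <- matrix(stats::rnorm(400), 50, 8)
  for (arch in c("cnn1d", "cnn2d", "lstm", "convlstm")) {
    sizes <- if (arch == "convlstm") c(4, 5, 6, 7) else c(4, 5)
    m <- build_model(model_config(arch, sizes, seed = 3))
    fw <- forward_sample(m, x)
    gr <- backward_sample(m, fw$cache, 1)
    for (nm in names(m$params)) {
      idx <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
      for (j in idx) {
        eps <- 1e-6
        mp <- m; mp$params[[nm]][j] <- m$params[[nm]][j] + eps
        mm <- m; mm$params[[nm]][j] <- m$params[[nm]][j] - eps
        num <- (forward_sample(mp, x)$yhat - forward_sample(mm, x)$yhat) / (2 * eps)
        expect_equal(gr[[nm]][j], num, tolerance = 1e-4,
                     label = paste(arch, nm, j))
      }
    }
  }
})

test_that("training a constant-target toy set converges to the target", {
  ws <- make_constant_windows(40, target = 5, seed = 61)
  fit <- train_regressor(model_config("convlstm", c(16, 16, 16, 16),
                                      loss = "MAE", max_epochs = 30,
                                      patience = 30, seed = 4), ws)
  pred <- predict(fit, ws)
  expect_true(all(abs(pred - 5) < 0.5))
  expect_lt(fit$best_val, 0.5)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(is.finite(fit$history$val_loss)))
})

test_that("early stopping halts on plateaued validation loss and restores the best epoch", {
  # pure-noise targets: nothing to learn, validation loss plateaus fast
  ws <- make_constant_windows(30, target = 0, seed = 62)
  ws$y <- stats::rnorm(30)
  fit <- train_regressor(model_config("cnn1d", c(8, 8), loss = "MAE",
                                      max_epochs = 100, patience = 5,
                                      seed = 5), ws)
  expect_lt(fit$stopped_epoch, 100L)
  expect_lte(fit$stopped_epoch, nrow(fit$history))
  # best-so-far validation loss is non-increasing and equals the stored best
  expect_equal(min(fit$history$val_loss), fit$best_val)
  expect_true(all(diff(cummin(fit$history$val_loss)) <= 0))
})

test_that("identical config and seed reproduce identical fits", {
  ws <- make_constant_windows(25, target = 3, seed = 63)
  cfg <- model_config("lstm", c(8, 8), loss = "MSE", max_epochs = 5,
                      patience = 5, seed = 6)
  f1 <- train_regressor(cfg, ws)
  f2 <- train_regressor(cfg, ws)
  expect_identical(f1$best_val, f2$best_val)
  expect_identical(f1$params, f2$params)
})

test_that("prediction preserves order, handles empty input and rejects bad shapes", {
  ws <- make_constant_windows(12, target = 2, seed = 64)
  fit <- train_regressor(model_config("cnn1d", c(8, 8), max_epochs = 3,
                                      patience = 3, seed = 7), ws)
  pred <- predict(fit, ws)
  expect_length(pred, 12L)
  expect_true(all(is.finite(pred)))
  expect_identical(predict(fit, subset_windows(ws, integer(0))), numeric(0))

  bad <- ws
  bad$x <- bad$x[, 1:40, , drop = FALSE]
  expect_error(predict(fit, bad), "50 x 8")
  expect_error(train_regressor(model_config("cnn1d", c(8, 8)),
                               subset_windows(ws, 1:5)),
               "at least 10")
})

test_that("checkpoints round-trip through disk with identical predictions", {
  ws <- make_constant_windows(15, target = 4, seed = 65)
  fit <- train_regressor(model_config("convlstm", c(16, 16, 16, 16),
                                      max_epochs = 3, patience = 3,
                                      seed = 8), ws)
  path <- withr::local_tempfile(fileext = ".rds")
  save_regressor(fit, path)
  back <- load_regressor(path)
  expect_identical(predict(back, ws), predict(fit, ws))
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("all architectures learn the separable ASVM-max toy task", {
  tr <- make_toy_windows(160, seed = 5)
  te <- make_toy_windows(40, seed = 6)
  baseline <- mean(abs(te$y - mean(tr$y)))     # constant predictor
  for (arch in c("cnn1d", "cnn2d", "lstm", "convlstm")) {
    sizes <- if (arch == "convlstm") c(16, 16, 16, 16) else c(16, 16)
    fit <- train_regressor(model_config(arch, sizes, loss = "MAE", seed = 4),
                           tr)
    test_mae <- mean(abs(predict(fit, te) - te$y))
    expect_lt(test_mae, 0.5)
    expect_lt(test_mae, baseline)
  }
})
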