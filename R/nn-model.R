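#' Configuration of a peak-acceleration regressor
#'
#' Fixes the architecture, the per-layer filter/unit counts, the training
#' loss and the training schedule. Defaults follow the study protocol:
#' batch size 1, ReLU hidden activations, dropout 0.25 before the single
#' linear output unit, early stopping on validation loss, 200 epochs with
#' patience 100 for the two CNNs and 50 epochs with patience 10 for the two
#' recurrent models.
#'
#' @param architecture One of `"cnn1d"`, `"cnn2d"`, `"lstm"`, `"convlstm"`.
#' @param layer_sizes Integer vector of filter/unit counts: two entries for
#'   `cnn1d`/`cnn2d`/`lstm`, four for `convlstm` (conv1, conv2, lstm1,
#'   lstm2).
#' @param loss `"MAE"` or `"MSE"` (the training objective; errors reported
#'   in g and g^2 respectively).
#' @param max_epochs,patience Training schedule; `NULL` picks the
#'   architecture default above.
#' @param batch_size Gradient-update batch size (default 1).
#' @param seed Integer seed covering weight initialization, the validation
#'   split, shuffling and dropout.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param val_frac Fraction of the training windows held out for early
#'   stopping (default 0.2, stratified by movement category).
#' @param dropout Dropout rate before the output (default 0.25).
#' @return An `ffh_model_config`.
#' @export
model_config <- function(architecture, layer_sizes, loss = c("MAE", "MSE"),
                         max_epochs = NULL, patience = NULL, batch_size = 1L,
                         seed = 1L, learning_rate = 1e-3, val_frac = 0.2,
                         dropout = 0.25) {
  architecture <- match.arg(architecture, c("cnn1d", "cnn2d", "lstm", "convlstm"))
  loss <- match.arg(loss)
  need <- if (architecture == "convlstm") 4L else 2L
  if (length(layer_sizes) != need) {
    stop(architecture, " requires ", need, " layer sizes, got ",
         length(layer_sizes))
  }
  if (any(!is.finite(layer_sizes)) || any(layer_sizes < 1)) {
    stop("layer_sizes must be positive integers")
  }
  if (is.null(max_epochs)) {
    max_epochs <- if (architecture %in% c("cnn1d", "cnn2d")) 200L else 50L
  }
  if (is.null(patience)) {
    patience <- if (architecture %in% c("cnn1d", "cnn2d")) 100L else 10L
  }
  structure(
    list(architecture = architecture, layer_sizes = as.integer(layer_sizes),
         loss = loss, max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), batch_size = as.integer(batch_size),
         seed = as.integer(seed), learning_rate = learning_rate,
         val_frac = val_frac, dropout = dropout),
    class = "ffh_model_config"
  )
}

#' Build an untrained regressor
#'
#' Instantiates the configured architecture with seeded Glorot-uniform
#' weights. All four models map one 50 x 8 pre-impact window to a single
#' linear output (the predicted peak acceleration in g):
#' \itemize{
#'   \item `cnn1d`: two blocks of (Conv1D kernel 2, stride 2, ReLU; max-pool
#'     2), time axis 50 -> 25 -> 12 -> 6 -> 3, then dropout and the output.
#'   \item `cnn2d`: the window as a 50 x 8 x 1 image; two blocks of (Conv2D
#'     kernel (4,4), stride (2,2), same padding, ReLU; max-pool (2,2)),
#'     50x8 -> 25x4 -> 12x2 -> 6x1 -> 3x1, then dropout and the output.
#'   \item `lstm`: two stacked LSTM layers over the 50-step sequence (second
#'     returns the last state), then dropout and the output.
#'   \item `convlstm`: the `cnn1d` convolution stack producing a 3-step
#'     feature sequence, two stacked LSTM layers, dropout, output.
#' }
#'
#' @param config An [model_config()].
#' @return An `ffh_model` with fields `config`, `params` and (for the
#'   2D-CNN) precomputed convolution geometry.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "ffh_model_config"))
  ls <- config$layer_sizes
  model <- with_local_seed(config$seed, {
    switch(config$architecture,
      cnn1d = {
        F1 <- ls[1]; F2 <- ls[2]
        list(params = list(
          W1 = glorot(16L, F1), b1 = numeric(F1),
          W2 = glorot(2L * F1, F2), b2 = numeric(F2),
          wd = glorot(3L * F2, 1L)[, 1], bd = 0
        ), flat_len = 3L * F2)
      },
      cnn2d = {
        F1 <- ls[1]; F2 <- ls[2]
        g1 <- conv2d_geom(50L, 8L, 1L)
        g2 <- conv2d_geom(12L, 2L, F1)
        list(params = list(
          W1 = glorot(16L, F1), b1 = numeric(F1),
          W2 = glorot(16L * F1, F2), b2 = numeric(F2),
          wd = glorot(3L * F2, 1L)[, 1], bd = 0
        ), g1 = g1, g2 = g2, flat_len = 3L * F2)
      },
      lstm = {
        U1 <- ls[1]; U2 <- ls[2]
        l1 <- lstm_init(8L, U1); l2 <- lstm_init(U1, U2)
        list(params = list(
          Wx1 = l1$Wx, Wh1 = l1$Wh, bl1 = l1$b,
          Wx2 = l2$Wx, Wh2 = l2$Wh, bl2 = l2$b,
          wd = glorot(U2, 1L)[, 1], bd = 0
        ), flat_len = U2)
      },
      convlstm = {
        F1 <- ls[1]; F2 <- ls[2]; U3 <- ls[3]; U4 <- ls[4]
        l3 <- lstm_init(F2, U3); l4 <- lstm_init(U3, U4)
        list(params = list(
          W1 = glorot(16L, F1), b1 = numeric(F1),
          W2 = glorot(2L * F1, F2), b2 = numeric(F2),
          Wx3 = l3$Wx, Wh3 = l3$Wh, bl3 = l3$b,
          Wx4 = l4$Wx, Wh4 = l4$Wh, bl4 = l4$b,
          wd = glorot(U4, 1L)[, 1], bd = 0
        ), flat_len = U4)
      }
    )
  })
  model$config <- config
  class(model) <- "ffh_model"
  model
}

#' Number of trainable parameters
#' @param model An `ffh_model` or `ffh_regressor`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# Single-sample forward pass. x: 50 x 8 matrix. drop_mask: NULL at inference,
# otherwise the inverted-dropout mask applied to the flat pre-output vector.
forward_sample <- function(model, x, drop_mask = NULL) {
  p <- model$params
  a <- model$config$architecture
  cache <- list()
  if (a %in% c("cnn1d", "convlstm")) {
    cache$c1 <- conv1d_fwd(x, p$W1, p$b1)
    cache$p1 <- pool1d_fwd(cache$c1$out)
    cache$c2 <- conv1d_fwd(cache$p1$out, p$W2, p$b2)
    cache$p2 <- pool1d_fwd(cache$c2$out)
    feat <- cache$p2$out                       # 3 x F2
  } else if (a == "cnn2d") {
    X <- array(x, c(50L, 8L, 1L))
    cache$c1 <- conv2d_fwd(X, p$W1, p$b1, model$g1)
    cache$p1 <- pool2d_fwd(cache$c1$out)
    cache$c2 <- conv2d_fwd(cache$p1$out, p$W2, p$b2, model$g2)
    cache$p2 <- pool2d_fwd(cache$c2$out)
    feat <- cache$p2$out                       # 3 x 1 x F2
  }
  if (a == "lstm") {
    cache$l1 <- lstm_fwd(x, p$Wx1, p$Wh1, p$bl1, return_seq = TRUE)
    cache$l2 <- lstm_fwd(cache$l1$out, p$Wx2, p$Wh2, p$bl2, return_seq = FALSE)
    flat <- cache$l2$out
  } else if (a == "convlstm") {
    cache$l3 <- lstm_fwd(feat, p$Wx3, p$Wh3, p$bl3, return_seq = TRUE)
    cache$l4 <- lstm_fwd(cache$l3$out, p$Wx4, p$Wh4, p$bl4, return_seq = FALSE)
    flat <- cache$l4$out
  } else {
    flat <- as.vector(feat)
  }
  if (!is.null(drop_mask)) flat <- flat * drop_mask
  cache$flat <- flat
  cache$drop_mask <- drop_mask
  yhat <- sum(flat * p$wd) + p$bd
  list(yhat = yhat, cache = cache)
}

# Backward pass for one sample; dy = d(loss)/d(yhat). Returns gradients
# named like the parameter list.
backward_sample <- function(model, cache, dy) {
  p <- model$params
  a <- model$config$architecture
  g <- list(wd = dy * cache$flat, bd = dy)
  dflat <- dy * p$wd
  if (!is.null(cache$drop_mask)) dflat <- dflat * cache$drop_mask
  if (a == "lstm") {
    b2 <- lstm_bwd(dflat, cache$l2, p$Wx2, p$Wh2)
    b1 <- lstm_bwd(b2$dX, cache$l1, p$Wx1, p$Wh1)
    g$Wx2 <- b2$dWx; g$Wh2 <- b2$dWh; g$bl2 <- b2$db
    g$Wx1 <- b1$dWx; g$Wh1 <- b1$dWh; g$bl1 <- b1$db
    return(g)
  }
  if (a == "convlstm") {
    b4 <- lstm_bwd(dflat, cache$l4, p$Wx4, p$Wh4)
    b3 <- lstm_bwd(b4$dX, cache$l3, p$Wx3, p$Wh3)
    g$Wx4 <- b4$dWx; g$Wh4 <- b4$dWh; g$bl4 <- b4$db
    g$Wx3 <- b3$dWx; g$Wh3 <- b3$dWh; g$bl3 <- b3$db
    dfeat <- b3$dX                              # 3 x F2
  } else if (a == "cnn1d") {
    dfeat <- matrix(dflat, nrow = 3L)
  } else {                                      # cnn2d
    dfeat <- array(dflat, c(3L, 1L, length(dflat) / 3L))
  }
  if (a == "cnn2d") {
    dp2 <- pool2d_bwd(dfeat, cache$p2)
    bc2 <- conv2d_bwd(dp2, cache$c2, p$W2, model$g2)
    dp1 <- pool2d_bwd(bc2$dX, cache$p1)
    bc1 <- conv2d_bwd(dp1, cache$c1, p$W1, model$g1)
  } else {
    dp2 <- pool1d_bwd(dfeat, cache$p2)
    bc2 <- conv1d_bwd(dp2, cache$c2, p$W2)
    dp1 <- pool1d_bwd(bc2$dX, cache$p1)
    bc1 <- conv1d_bwd(dp1, cache$c1, p$W1)
  }
  g$W2 <- bc2$dW; g$b2 <- bc2$db
  g$W1 <- bc1$dW; g$b1 <- bc1$db
  g
}

loss_value <- function(err, loss) if (loss == "MAE") mean(abs(err)) else mean(err^2)

mean_loss_on <- function(model, x, y, loss) {
  n <- dim(x)[1]
  pred <- vapply(seq_len(n),
                 function(i) forward_sample(model, x[i, , ])$yhat, numeric(1))
  loss_value(pred - y, loss)
}

#' Train a regressor with batch-size-1 gradient descent and early stopping
#'
#' Optimizes the configured loss (MAE or MSE) with Adam at the configured
#' learning rate, one window per gradient update. A seeded validation subset
#' (20% of the training windows, stratified by movement category) is
#' monitored after every epoch; training stops once the validation loss has
#' not improved for `patience` consecutive epochs, and the best-epoch
#' weights are restored. Identical config and seed reproduce identical fits
#' on one machine.
#'
#' @param config An [model_config()].
#' @param train_ws Training `ffh_window_set` (at least 10 windows).
#' @param verbose Print per-epoch losses.
#' @return An `ffh_regressor`: the fitted model plus `history` (data frame
#'   `epoch`, `train_loss`, `val_loss`), `stopped_epoch` and `best_val`.
#' @export
train_regressor <- function(config, train_ws, verbose = FALSE) {
  stopifnot(inherits(config, "ffh_model_config"),
            inherits(train_ws, "ffh_window_set"))
  n <- dim(train_ws$x)[1]
  if (n < 10L) stop("need at least 10 training windows, got ", n)
  model <- build_model(config)

  fit <- with_local_seed((config$seed + 1) %% 2147483647, {
    # Validation subset for early stopping, stratified by category.
    strata <- if (!is.null(train_ws$meta$category)) {
      train_ws$meta$category
    } else {
      rep("all", n)
    }
    val_idx <- integer(0)
    for (s in sort(unique(strata))) {
      ids <- which(strata == s)
      k <- max(1L, floor(config$val_frac * length(ids)))
      val_idx <- c(val_idx, sample(ids, k))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    xt <- train_ws$x[tr_idx, , , drop = FALSE]
    yt <- train_ws$y[tr_idx]
    xv <- train_ws$x[val_idx, , , drop = FALSE]
    yv <- train_ws$y[val_idx]
    n_tr <- length(tr_idx)

    # Adam state
    mstate <- lapply(model$params, function(p) p * 0)
    vstate <- lapply(model$params, function(p) p * 0)
    step <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate
    rate <- config$dropout

    best_val <- Inf
    best_params <- model$params
    wait <- 0L
    history <- vector("list", config$max_epochs)
    stopped <- config$max_epochs

    acc_grads <- NULL
    in_batch <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample(n_tr)
      ep_loss <- 0
      for (i in perm) {
        mask <- if (rate > 0) {
          (stats::runif(model$flat_len) >= rate) / (1 - rate)
        } else {
          NULL
        }
        fw <- forward_sample(model, xt[i, , ], drop_mask = mask)
        err <- fw$yhat - yt[i]
        if (!is.finite(err)) {
          stop("non-finite training loss at epoch ", epoch,
               " (architecture ", config$architecture, ")")
        }
        ep_loss <- ep_loss + if (config$loss == "MAE") abs(err) else err^2
        dy <- if (config$loss == "MAE") sign(err) else 2 * err
        gr <- backward_sample(model, fw$cache, dy)
        if (is.null(acc_grads)) {
          acc_grads <- gr
        } else {
          for (nm in names(gr)) acc_grads[[nm]] <- acc_grads[[nm]] + gr[[nm]]
        }
        in_batch <- in_batch + 1L
        if (in_batch >= config$batch_size) {
          step <- step + 1L
          sc <- 1 / in_batch
          for (nm in names(acc_grads)) {
            gnm <- acc_grads[[nm]] * sc
            mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gnm
            vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gnm^2
            mh <- mstate[[nm]] / (1 - b1^step)
            vh <- vstate[[nm]] / (1 - b2^step)
            model$params[[nm]] <- model$params[[nm]] - lr * mh / (sqrt(vh) + eps)
          }
          acc_grads <- NULL
          in_batch <- 0L
        }
      }
      val <- mean_loss_on(model, xv, yv, config$loss)
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = ep_loss / n_tr,
                                     val_loss = val)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        ep_loss / n_tr, val))
      }
      if (val < best_val) {
        best_val <- val
        best_params <- model$params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) {
          stopped <- epoch
          break
        }
      }
      stopped <- epoch
    }
    model$params <- best_params
    list(model = model, history = do.call(rbind, history[!vapply(history, is.null, logical(1))]),
         stopped_epoch = stopped, best_val = best_val)
  })

  structure(
    list(config = config, params = fit$model$params,
         g1 = fit$model$g1, g2 = fit$model$g2, flat_len = fit$model$flat_len,
         history = fit$history, stopped_epoch = fit$stopped_epoch,
         best_val = fit$best_val),
    class = "ffh_regressor"
  )
}

#' Predict peak accelerations for a set of windows
#'
#' @param object An `ffh_regressor`.
#' @param ws An `ffh_window_set` (order preserved in the output).
#' @param ... Unused.
#' @return Numeric vector of predicted peaks in g, one per window.
#' @export
predict.ffh_regressor <- function(object, ws, ...) {
  stopifnot(inherits(ws, "ffh_window_set"))
  n <- dim(ws$x)[1]
  if (n == 0L) return(numeric(0))
  if (dim(ws$x)[2] != 50L || dim(ws$x)[3] != 8L) {
    stop("windows must be 50 x 8, got ",
         dim(ws$x)[2], " x ", dim(ws$x)[3])
  }
  shim <- list(params = object$params, config = object$config,
               g1 = object$g1, g2 = object$g2, flat_len = object$flat_len)
  vapply(seq_len(n), function(i) forward_sample(shim, ws$x[i, , ])$yhat,
         numeric(1))
}

#' @export
print.ffh_regressor <- function(x, ...) {
  cat(sprintf("<ffh_regressor> %s (%s loss), layers [%s], %d params, stopped at epoch %d, best val %.4f\n",
              x$config$architecture, x$config$loss,
              paste(x$config$layer_sizes, collapse = ","),
              count_params(x), x$stopped_epoch, x$best_val))
  invisible(x)
}

#' Save / load a fitted regressor with a JSON config sidecar
#' @param object An `ffh_regressor`.
#' @param path Checkpoint path (an `.rds`; `<path>.json` holds the config
#'   and training summary).
#' @export
save_regressor <- function(object, path) {
  stopifnot(inherits(object, "ffh_regressor"))
  saveRDS(object, path)
  side <- list(architecture = object$config$architecture,
               layer_sizes = object$config$layer_sizes,
               loss = object$config$loss, seed = object$config$seed,
               stopped_epoch = object$stopped_epoch,
               best_val = object$best_val, n_params = count_params(object))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_regressor
#' @export
load_regressor <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "ffh_regressor"))
  obj
}
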