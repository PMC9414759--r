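#' Layer-size grids for the grid search
#'
#' The CNNs and the LSTM search both layer sizes over {8, 16, 32, 64}
#' (16 combinations); the Conv-LSTM searches its two convolution filter
#' counts and two LSTM unit counts over {16, 64} (2^4 = 16 combinations).
#'
#' @param architecture One of `"cnn1d"`, `"cnn2d"`, `"lstm"`, `"convlstm"`.
#' @return A data frame with one row per grid point and columns
#'   `size1`, `size2` (and `size3`, `size4` for `convlstm`).
#' @export
enumerate_grid <- function(architecture) {
  architecture <- match.arg(architecture, c("cnn1d", "cnn2d", "lstm", "convlstm"))
  if (architecture == "convlstm") {
    g <- expand.grid(size1 = c(16L, 64L), size2 = c(16L, 64L),
                     size3 = c(16L, 64L), size4 = c(16L, 64L))
  } else {
    g <- expand.grid(size1 = c(8L, 16L, 32L, 64L), size2 = c(8L, 16L, 32L, 64L))
  }
  g <- g[do.call(order, g), , drop = FALSE]
  rownames(g) <- NULL
  g
}

grid_sizes <- function(grid_row) as.integer(unlist(grid_row))

#' Exhaustive grid search over layer sizes
#'
#' Trains one regressor per grid point with a shared seed (hence an
#' identical validation split) and ranks the points by validation error in
#' the training loss's own units. Ties resolve to the configuration with
#' fewer trainable parameters, then to the lexicographically smaller layer
#' sizes. A failed training run is recorded for its row (error `NA`) rather
#' than aborting the search; the search fails only if every row fails.
#'
#' @param architecture,loss Passed to [model_config()].
#' @param train_ws Training `ffh_window_set`.
#' @param seed Shared seed for every grid point.
#' @param evaluator Optional function `(config) -> list(val_error,
#'   stopped_epoch)` replacing actual training; used for selection testing
#'   and custom backends.
#' @param ... Further arguments to [model_config()] (e.g. `max_epochs`).
#' @return An `ffh_grid_result`: list with `table` (one row per grid point:
#'   sizes, `val_error`, `stopped_epoch`, `n_params`, `selected`) and
#'   `best` (the selected [model_config()]).
#' @export
grid_search <- function(architecture, loss = "MAE", train_ws = NULL,
                        seed = 1L, evaluator = NULL, ...) {
  grid <- enumerate_grid(architecture)
  if (is.null(evaluator)) {
    if (is.null(train_ws) || dim(train_ws$x)[1] == 0L) {
      stop("grid_search needs nonempty training windows (or an evaluator)")
    }
    evaluator <- function(config) {
      fit <- train_regressor(config, train_ws)
      list(val_error = fit$best_val, stopped_epoch = fit$stopped_epoch)
    }
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sizes <- grid_sizes(grid[i, ])
    config <- model_config(architecture, sizes, loss = loss, seed = seed, ...)
    n_par <- count_params(build_model(config))
    res <- tryCatch(evaluator(config), error = function(e) {
      warning("grid point [", paste(sizes, collapse = ","), "] failed: ",
              conditionMessage(e))
      list(val_error = NA_real_, stopped_epoch = NA_integer_)
    })
    rows[[i]] <- cbind(grid[i, , drop = FALSE],
                       data.frame(val_error = res$val_error,
                                  stopped_epoch = res$stopped_epoch,
                                  n_params = n_par))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (all(is.na(tab$val_error))) stop("every grid point failed to train")

  size_cols <- grep("^size", names(tab), value = TRUE)
  ord <- do.call(order, c(list(tab$val_error, tab$n_params),
                          tab[size_cols], list(na.last = TRUE)))
  best_i <- ord[1]
  tab$selected <- seq_len(nrow(tab)) == best_i
  best_cfg <- model_config(architecture, grid_sizes(tab[best_i, size_cols]),
                           loss = loss, seed = seed, ...)
  structure(list(table = tab, best = best_cfg, architecture = architecture,
                 loss = loss),
            class = "ffh_grid_result")
}

#' Write a grid-search result table as CSV
#' @param result An `ffh_grid_result`.
#' @param path Output CSV path.
#' @export
write_grid_result <- function(result, path) {
  tab <- result$table
  tab <- cbind(data.frame(architecture = result$architecture,
                          loss = result$loss), tab)
  data.table::fwrite(tab, path)
  invisible(tab)
}
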