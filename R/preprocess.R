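#' Sum vector magnitude of a 3-axis signal
#'
#' The Euclidean norm sqrt(x^2 + y^2 + z^2) of the three sensor axes at each
#' sample, the standard magnitude feature for body-worn accelerometers and
#' gyroscopes (acceleration SVM in g, gyro SVM in deg/s). Vectorized over
#' samples.
#'
#' @param x,y,z Numeric vectors of equal length (one element per sample).
#' @return Nonnegative numeric vector of the same length.
#' @examples
#' compute_svm(3, 4, 12)  # 13
#' @export
compute_svm <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z)) {
    stop("x, y and z must have equal length")
  }
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
    stop("compute_svm requires finite inputs")
  }
  sqrt(x^2 + y^2 + z^2)
}

asvm_of <- function(recording) {
  d <- recording$data
  compute_svm(d$acc_x_g, d$acc_y_g, d$acc_z_g)
}

#' Locate the impact peak of a recording
#'
#' The peak is the global maximum of the per-sample acceleration SVM; exact
#' ties resolve to the earliest sample.
#'
#' @param recording An `ffh_recording`.
#' @return List with `peak_index` (1-based sample index) and `peak_value_g`.
#' @export
find_peak <- function(recording) {
  stopifnot(inherits(recording, "ffh_recording"))
  a <- asvm_of(recording)
  if (length(a) == 0L) stop("recording has no samples")
  i <- which.max(a)          # earliest index on exact ties
  list(peak_index = i, peak_value_g = a[i])
}

#' Extract the pre-impact feature window
#'
#' Takes the 0.5 s of data from 0.7 s to 0.2 s before the impact peak: at
#' 100 Hz, the 50 samples starting 70 samples before the peak and ending 21
#' samples before it (half-open interval `[peak - 70, peak - 20)` in 0-based
#' indexing). Columns follow the fixed 8-feature order AX, AY, AZ, ASVM, GX,
#' GY, GZ, GSVM; the regression target is the recording's true peak
#' acceleration SVM in g, which always lies at or above the window's own
#' ASVM maximum since the window closes 0.2 s before the peak.
#'
#' @param recording An `ffh_recording`.
#' @param peak_index 1-based peak sample index; defaults to
#'   [find_peak()]'s result.
#' @return An `ffh_window`: list with `matrix` (50 x 8), `target_peak` (g),
#'   `movement_code`, `category`, `recording_id`.
#' @export
extract_window <- function(recording, peak_index = NULL) {
  stopifnot(inherits(recording, "ffh_recording"))
  pk <- find_peak(recording)
  if (is.null(peak_index)) peak_index <- pk$peak_index
  if (peak_index - 1L < 70L) {
    stop("insufficient pre-peak history (need 70 samples before the peak) in recording ",
         recording_id(recording$movement_code, recording$subject_id,
                      recording$trial_index))
  }
  rows <- seq.int(peak_index - 70L, peak_index - 21L)
  d <- recording$data[rows, ]
  m <- cbind(
    AX = d$acc_x_g, AY = d$acc_y_g, AZ = d$acc_z_g,
    ASVM = compute_svm(d$acc_x_g, d$acc_y_g, d$acc_z_g),
    GX = d$gyro_x_dps, GY = d$gyro_y_dps, GZ = d$gyro_z_dps,
    GSVM = compute_svm(d$gyro_x_dps, d$gyro_y_dps, d$gyro_z_dps)
  )
  rownames(m) <- NULL
  stopifnot(nrow(m) == 50L, ncol(m) == 8L, all(is.finite(m)))
  structure(
    list(matrix = m, target_peak = pk$peak_value_g,
         movement_code = recording$movement_code,
         category = recording$category,
         recording_id = recording_id(recording$movement_code,
                                     recording$subject_id,
                                     recording$trial_index)),
    class = "ffh_window"
  )
}

#' Build the window set of a dataset
#'
#' Applies [find_peak()] and [extract_window()] to every recording (one
#' window per recording) and stacks the results into a model-ready
#' container.
#'
#' @param dataset An `ffh_dataset`.
#' @return An `ffh_window_set`: list with `x` (array n x 50 x 8), `y`
#'   (numeric targets in g) and `meta` (data frame with `recording_id`,
#'   `movement_code`, `category`, `performer`, `subject_id`).
#' @export
build_windows <- function(dataset) {
  stopifnot(inherits(dataset, "ffh_dataset"))
  recs <- dataset$recordings
  n <- length(recs)
  if (n == 0L) stop("dataset contains no recordings")
  x <- array(NA_real_, dim = c(n, 50L, 8L),
             dimnames = list(NULL, NULL,
                             c("AX", "AY", "AZ", "ASVM", "GX", "GY", "GZ", "GSVM")))
  y <- numeric(n)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    w <- extract_window(recs[[i]])
    x[i, , ] <- w$matrix
    y[i] <- w$target_peak
    meta[[i]] <- data.frame(
      recording_id = w$recording_id, movement_code = w$movement_code,
      category = w$category, performer = recs[[i]]$performer,
      subject_id = recs[[i]]$subject_id, stringsAsFactors = FALSE
    )
  }
  structure(list(x = x, y = y, meta = do.call(rbind, meta)),
            class = "ffh_window_set")
}

#' Subset a window set by index or logical mask
#' @param ws An `ffh_window_set`.
#' @param idx Integer or logical index over windows.
#' @return The reduced `ffh_window_set`.
#' @export
subset_windows <- function(ws, idx) {
  structure(list(x = ws$x[idx, , , drop = FALSE], y = ws$y[idx],
                 meta = ws$meta[idx, , drop = FALSE]),
            class = "ffh_window_set")
}

#' Train/test split stratified by movement
#'
#' Assigns 70% of human recordings and 60% of dummy recordings to the
#' training set (the remainder to testing), sampling within each movement
#' code so no movement is starved. Per stratum the training count is
#' `floor(fraction * stratum size)`.
#'
#' @param manifest Manifest data frame (see [generate_dataset()]).
#' @param human_frac,dummy_frac Training fractions in (0, 1).
#' @param seed Integer seed.
#' @return An `ffh_split`: list with `train_ids`, `test_ids` and `seed`.
#' @export
split_dataset <- function(manifest, human_frac = 0.7, dummy_frac = 0.6,
                          seed = 1L) {
  if (is.null(manifest) || nrow(manifest) == 0L) stop("manifest is empty")
  for (f in c("human_frac", "dummy_frac")) {
    v <- get(f)
    stopifnot_scalar_finite(v, f)
    if (v <= 0 || v >= 1) stop("field '", f, "' must lie strictly in (0, 1)")
  }
  train_ids <- character(0)
  with_local_seed(seed, {
    for (code in sort(unique(manifest$movement_code))) {
      stratum <- manifest[manifest$movement_code == code, ]
      frac <- if (stratum$performer[1] == "human") human_frac else dummy_frac
      n_tr <- floor(frac * nrow(stratum))
      picked <- sample(stratum$recording_id, n_tr)
      train_ids <- c(train_ids, picked)
    }
  })
  structure(
    list(train_ids = sort(train_ids),
         test_ids = sort(setdiff(manifest$recording_id, train_ids)),
         seed = as.integer(seed)),
    class = "ffh_split"
  )
}

#' Write / read a split assignment as a two-column CSV
#' @param split An `ffh_split`.
#' @param path Output CSV path (columns `recording_id`, `split`).
#' @export
write_split <- function(split, path) {
  df <- rbind(
    data.frame(recording_id = split$train_ids, split = "train"),
    data.frame(recording_id = split$test_ids, split = "test")
  )
  data.table::fwrite(df, path)
  invisible(df)
}

#' Per-channel z-scoring fitted on training windows
#'
#' Channel-wise standardization (mean 0, SD 1 over all training samples and
#' time steps) fitted on the training split only and applied unchanged to
#' test data. Useful because the gyro channels are two orders of magnitude
#' larger than the acceleration channels.
#'
#' @param ws Training `ffh_window_set`.
#' @return An `ffh_normalizer` with per-channel `mean` and `sd`.
#' @export
fit_normalizer <- function(ws) {
  stopifnot(inherits(ws, "ffh_window_set"))
  mu <- apply(ws$x, 3, mean)
  sdv <- apply(ws$x, 3, stats::sd)
  sdv[sdv < 1e-8] <- 1
  structure(list(mean = mu, sd = sdv), class = "ffh_normalizer")
}

#' @rdname fit_normalizer
#' @param norm An `ffh_normalizer`.
#' @export
apply_normalizer <- function(norm, ws) {
  stopifnot(inherits(norm, "ffh_normalizer"), inherits(ws, "ffh_window_set"))
  for (c in seq_len(dim(ws$x)[3])) {
    ws$x[, , c] <- (ws$x[, , c] - norm$mean[c]) / norm$sd[c]
  }
  ws
}

#' Arrange windows as a model-ready batch
#'
#' The 1D-CNN, LSTM and Conv-LSTM consume each window as a 50-step sequence
#' of 8 features; the 2D-CNN consumes it as a single-channel 50 x 8 image
#' (array n x 50 x 8 x 1). Target pairing is preserved.
#'
#' @param ws An `ffh_window_set`.
#' @param architecture One of `"cnn1d"`, `"cnn2d"`, `"lstm"`, `"convlstm"`.
#' @return List with `x` (array), `y`, `meta`.
#' @export
assemble_inputs <- function(ws, architecture) {
  stopifnot(inherits(ws, "ffh_window_set"))
  architecture <- match.arg(architecture, c("cnn1d", "cnn2d", "lstm", "convlstm"))
  n <- dim(ws$x)[1]
  if (n == 0L) stop("no windows to assemble")
  bad <- which(apply(ws$x, 1, function(m) !all(is.finite(m))))
  if (length(bad)) {
    stop("malformed window for recording ",
         paste(ws$meta$recording_id[bad], collapse = ", "))
  }
  x <- if (architecture == "cnn2d") {
    array(ws$x, dim = c(n, 50L, 8L, 1L))
  } else {
    ws$x
  }
  list(x = x, y = ws$y, meta = ws$meta)
}
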