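# Shared fixture builders; everything is generated in code at test time.

# Wrap raw acceleration/gyro matrices (n x 3 each) as an ffh_recording.
make_recording <- function(acc, gyro = NULL, code = "NF01", category = "NF",
                           performer = "human", subject = "S01", trial = 1L) {
  n <- nrow(acc)
  if (is.null(gyro)) gyro <- matrix(0, n, 3)
  structure(
    list(data = data.frame(
           time_s = (seq_len(n) - 1) / 100,
           acc_x_g = acc[, 1], acc_y_g = acc[, 2], acc_z_g = acc[, 3],
           gyro_x_dps = gyro[, 1], gyro_y_dps = gyro[, 2],
           gyro_z_dps = gyro[, 3]),
         sampling_rate = 100, movement_code = code, category = category,
         performer = performer, subject_id = subject,
         trial_index = as.integer(trial), seed = 0L, drawn_peak_g = NA_real_),
    class = "ffh_recording"
  )
}

# Window set with arbitrary content and a constant regression target.
make_constant_windows <- function(n, target = 5, seed = 1) {
  set.seed(seed)
  structure(
    list(x = array(stats::rnorm(n * 50 * 8), c(n, 50, 8)),
         y = rep(target, n),
         meta = data.frame(recording_id = sprintf("R%03d", seq_len(n)),
                           movement_code = "NF01",
                           category = rep(c("NF", "LF"), length.out = n),
                           performer = "human", subject_id = "S01")),
    class = "ffh_window_set"
  )
}

# Separable toy task: oscillatory acceleration with a random amplitude, a
# consistent ASVM column, and target = window ASVM max + 1 (learnable from
# the input alone).
make_toy_windows <- function(n, seed) {
  set.seed(seed)
  x <- array(0, c(n, 50, 8))
  y <- numeric(n)
  for (i in seq_len(n)) {
    amp <- stats::runif(1, 0.5, 3)
    acc <- vapply(1:3, function(j) {
      amp * sin(2 * pi * stats::runif(1, 1, 3) * (1:50) / 100 +
                  stats::runif(1, 0, 6)) + stats::rnorm(50, 0, 0.1)
    }, numeric(50))
    gy <- matrix(stats::rnorm(150), 50, 3)
    asvm <- sqrt(rowSums(acc^2))
    x[i, , ] <- cbind(acc, asvm, gy, sqrt(rowSums(gy^2)))
    y[i] <- max(asvm) + 1
  }
  structure(
    list(x = x, y = y,
         meta = data.frame(recording_id = sprintf("T%03d", seq_len(n)),
                           movement_code = "NF01",
                           category = rep(c("NF", "LF"), length.out = n),
                           performer = "human", subject_id = "S01")),
    class = "ffh_window_set"
  )
}

# Measured duration of the contiguous near-zero specific-force run ending
# just before the peak (free-fall detector used against sqrt(2h/g)).
measured_freefall_s <- function(rec, threshold_g = 0.5) {
  a <- compute_svm(rec$data$acc_x_g, rec$data$acc_y_g, rec$data$acc_z_g)
  p <- which.max(a)
  i <- p - 2L
  k <- 0L
  while (i > 0 && a[i] < threshold_g) {
    k <- k + 1L
    i <- i - 1L
  }
  k / rec$sampling_rate
}
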