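#' Specification of a synthetic IMU dataset
#'
#' Mirrors the study design the generator emulates: each human subject
#' performs every human movement three times, and the dummy repeats each
#' dummy-performed fall five times. The master seed fully determines every
#' generated sample; each recording draws from an independent substream
#' derived from (movement, subject, trial), so generation order is
#' irrelevant.
#'
#' @param n_subjects Number of synthetic human subjects (default 20).
#' @param human_trials Repetitions per human movement per subject (default 3).
#' @param dummy_trials Repetitions per dummy movement (default 5).
#' @param master_seed Integer master seed.
#' @param overrides Optional named list of per-movement profile overrides,
#'   e.g. `list(HF05 = list(peak_mean = 14))`.
#' @return An object of class `ffh_dataset_spec`.
#' @export
dataset_spec <- function(n_subjects = 20L, human_trials = 3L,
                         dummy_trials = 5L, master_seed = 1L,
                         overrides = NULL) {
  for (f in c("n_subjects", "human_trials", "dummy_trials")) {
    v <- get(f)
    stopifnot_scalar_finite(v, f)
    if (v < 1 || v != trunc(v)) {
      stop("field '", f, "' must be a positive integer")
    }
  }
  stopifnot_scalar_finite(master_seed, "master_seed")
  structure(
    list(n_subjects = as.integer(n_subjects),
         human_trials = as.integer(human_trials),
         dummy_trials = as.integer(dummy_trials),
         master_seed = as.integer(master_seed),
         overrides = overrides),
    class = "ffh_dataset_spec"
  )
}

apply_overrides <- function(profiles, overrides) {
  if (is.null(overrides)) return(profiles)
  for (code in names(overrides)) {
    if (!code %in% profiles$code) stop("override for unknown movement code: ", code)
    for (f in names(overrides[[code]])) {
      if (!f %in% names(profiles)) stop("override names unknown field: ", f)
      profiles[profiles$code == code, f] <- overrides[[code]][[f]]
    }
    profiles[profiles$code == code, "has_free_fall"] <-
      profiles[profiles$code == code, "fall_height"] > 0
    validate_profile(profiles[profiles$code == code, ])
  }
  profiles
}

#' Generate one synthetic 6-axis IMU recording
#'
#' Produces a 5 s trunk-worn IMU trace at 100 Hz whose acceleration
#' sum-vector-magnitude (SVM) peaks exactly at a value drawn from the
#' movement profile's truncated-normal peak distribution. The waveform is
#' built from: a gravity baseline (about 1 g on a slightly tilted axis) plus
#' band-limited Gaussian noise; movement-specific low-frequency oscillations
#' whose amplitude scales with the drawn peak (more violent movements precede
#' larger impacts); for falls from height, a free-fall phase of duration
#' sqrt(2 h / 9.81) with near-zero specific force immediately before impact;
#' a 30 ms half-sine impact pulse realizing the drawn peak; and decaying
#' post-impact ringing. Gyroscope channels carry matched oscillations and,
#' during forward falls, tumbling bursts; vertical (feet-first) falls rotate
#' little.
#'
#' The construction guarantees that the global SVM maximum equals the drawn
#' peak (the rest of the trace is bounded strictly below it), so the drawn
#' value is recoverable by peak picking.
#'
#' @param profile One-row profile data frame (see [default_profiles()]).
#' @param subject_id Subject label, e.g. `"S01"` or `"D01"`.
#' @param trial_index Trial number (1-based).
#' @param seed Integer seed for this recording's RNG substream.
#' @param sampling_rate Sampling frequency in Hz (default 100).
#' @param duration_s Recording length in seconds (default 5).
#' @return An `ffh_recording`: list with `data` (data frame with columns
#'   `time_s`, `acc_x_g`, `acc_y_g`, `acc_z_g`, `gyro_x_dps`, `gyro_y_dps`,
#'   `gyro_z_dps`), `sampling_rate`, `movement_code`, `category`,
#'   `performer`, `subject_id`, `trial_index`, `seed` and `drawn_peak_g`.
#' @examples
#' rec <- generate_recording(get_profile("HF02"), "D01", 1, seed = 42)
#' max(compute_svm(rec$data$acc_x_g, rec$data$acc_y_g, rec$data$acc_z_g))
#' @export
generate_recording <- function(profile, subject_id, trial_index, seed,
                               sampling_rate = 100, duration_s = 5) {
  validate_profile(profile)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != trunc(seed)) {
    stop("field 'seed' must be a single finite integer")
  }
  fs <- sampling_rate
  n <- as.integer(round(duration_s * fs))
  if (n < 100L) stop("field 'duration_s' too short: need at least 100 samples")

  out <- with_local_seed(seed, {
    peak_g <- rtrunc_norm1(profile$peak_mean, profile$peak_sd,
                           profile$peak_min, profile$peak_max)
    # Peak placed in [2.5, 4.0] s: always >= 1 s after start, leaving the
    # full 0.7 s pre-impact history and post-impact room.
    p <- sample(seq.int(round(2.5 * fs) + 1L, round(4.0 * fs) + 1L), 1L)
    tt <- (seq_len(n) - 1L) / fs

    # Gravity baseline: unit vector with a small random tilt off +z.
    theta <- stats::runif(1L, 0, 0.12)
    phi <- stats::runif(1L, 0, 2 * pi)
    gvec <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))

    # Band-limited sensor noise (moving-average smoothed white noise).
    noise <- vapply(1:3, function(i) {
      z <- stats::rnorm(n, 0, 0.05)
      z <- stats::filter(z, rep(1 / 5, 5), sides = 2)
      z[is.na(z)] <- 0
      as.numeric(z)
    }, numeric(n))

    # Movement oscillation: amplitude tied to the drawn peak so pre-impact
    # intensity predicts impact severity; capped for free-fall movements,
    # where severity is carried by the fall height instead.
    amp <- 0.5 * (peak_g - 1)
    if (profile$has_free_fall) amp <- min(amp, 1.5)
    w <- stats::runif(3L, 0.2, 1)
    w <- w / sqrt(sum(w^2))
    ph <- stats::runif(3L, 0, 2 * pi)
    ph2 <- stats::runif(3L, 0, 2 * pi)
    f0 <- profile$activity_freq
    act <- vapply(1:3, function(i) {
      amp * w[i] * (sin(2 * pi * f0 * tt + ph[i]) +
                      0.35 * sin(2 * pi * 2 * f0 * tt + ph2[i]))
    }, numeric(n))

    dev <- act + noise
    # Post-impact ringing replaces the movement oscillation, decaying to rest.
    ring_idx <- seq.int(min(p + 2L, n), min(p + 60L, n))
    decay <- exp(-(seq_along(ring_idx) - 1L) / 12)
    ring_amp <- 0.4 * (peak_g - 1)
    for (i in 1:3) {
      dev[ring_idx, i] <- ring_amp * w[i] * decay *
        sin(2 * pi * 7 * tt[ring_idx] + ph[i]) + noise[ring_idx, i]
    }
    # Keep the off-peak SVM strictly below the drawn peak:
    # |g + d| <= 1 + |d| < peak whenever |d| <= 0.9 (peak - 1).
    dn <- sqrt(rowSums(dev^2))
    cap <- 0.9 * (peak_g - 1)
    mx <- max(dn)
    if (mx > cap) dev <- dev * (cap / mx)
    acc <- matrix(gvec, n, 3, byrow = TRUE) + dev

    # Gyro: movement oscillation scaled by the profile's characteristic
    # angular-velocity intensity, plus wideband noise.
    unit_p <- (peak_g - profile$peak_min) /
      max(profile$peak_max - profile$peak_min, 1e-9)
    ga <- min(profile$gyro_intensity * (0.6 + 0.4 * unit_p), 400)
    gw <- stats::runif(3L, 0.2, 1)
    gw <- gw / max(gw)
    gph <- stats::runif(3L, 0, 2 * pi)
    gyro <- vapply(1:3, function(i) {
      ga * gw[i] * sin(2 * pi * f0 * tt + gph[i]) + stats::rnorm(n, 0, 3)
    }, numeric(n))

    n_ff <- 0L
    if (profile$has_free_fall) {
      # Free fall: specific force near zero for sqrt(2h/g) seconds before
      # impact; forward falls tumble, vertical falls barely rotate.
      t_ff <- sqrt(2 * profile$fall_height / 9.81)
      n_ff <- as.integer(round(t_ff * fs))
      ff <- seq.int(p - n_ff, p - 1L)
      acc[ff, ] <- matrix(stats::rnorm(3L * n_ff, 0, 0.02), n_ff, 3)
      tumble <- min(profile$gyro_intensity, 400)
      gph_ff <- stats::runif(3L, 0, 2 * pi)
      for (i in 1:3) {
        gyro[ff, i] <- tumble * gw[i] * sin(2 * pi * 1.3 * tt[ff] + gph_ff[i]) +
          stats::rnorm(n_ff, 0, 2)
      }
    }

    # Gyro ringing decays to rest after the impact.
    for (i in 1:3) {
      gyro[ring_idx, i] <- ga * 0.5 * gw[i] * decay *
        sin(2 * pi * 5 * tt[ring_idx] + gph[i]) + stats::rnorm(length(ring_idx), 0, 3)
    }

    # Impact: 30 ms half-sine pulse whose apex realizes the drawn peak
    # exactly; neighbours are convex blends, hence strictly below it.
    impact_dir <- if (profile$has_free_fall && profile$gyro_intensity > 100) {
      c(0.85, stats::runif(1L, -0.2, 0.2), 0.5)      # forward fall: chest-first
    } else if (profile$has_free_fall) {
      c(stats::runif(1L, -0.1, 0.1), stats::runif(1L, -0.1, 0.1), 1) # feet-first
    } else {
      gvec + stats::runif(3L, -0.15, 0.15)
    }
    impact_dir <- impact_dir / sqrt(sum(impact_dir^2))
    env <- c(0.5, 1, 0.5)
    pulse_idx <- c(p - 1L, p, p + 1L)
    keep <- pulse_idx >= 1L & pulse_idx <= n
    for (k in which(keep)) {
      acc[pulse_idx[k], ] <- env[k] * peak_g * impact_dir +
        (1 - env[k]) * acc[pulse_idx[k], ]
    }
    gyro_spike <- min(profile$gyro_intensity, 400)
    gyro[p, ] <- gyro_spike * gw * sign(sin(gph + 1))

    list(acc = acc, gyro = gyro, peak_g = peak_g, p = p)
  })

  stopifnot(all(is.finite(out$acc)), all(is.finite(out$gyro)))
  data <- data.frame(
    time_s = (seq_len(n) - 1L) / fs,
    acc_x_g = out$acc[, 1], acc_y_g = out$acc[, 2], acc_z_g = out$acc[, 3],
    gyro_x_dps = out$gyro[, 1], gyro_y_dps = out$gyro[, 2],
    gyro_z_dps = out$gyro[, 3]
  )
  structure(
    list(data = data, sampling_rate = fs,
         movement_code = profile$code, category = profile$category,
         performer = profile$performer, subject_id = subject_id,
         trial_index = as.integer(trial_index), seed = as.integer(seed),
         drawn_peak_g = out$peak_g),
    class = "ffh_recording"
  )
}

#' @export
print.ffh_recording <- function(x, ...) {
  cat(sprintf("<ffh_recording> %s (%s, %s) subject %s trial %d: %d samples @ %g Hz, peak %.2f g\n",
              x$movement_code, x$category, x$performer, x$subject_id,
              x$trial_index, nrow(x$data), x$sampling_rate, x$drawn_peak_g))
  invisible(x)
}

recording_id <- function(code, subject_id, trial_index) {
  sprintf("%s_%s_T%02d", code, subject_id, trial_index)
}

#' Enumerate the recording manifest implied by a dataset spec
#'
#' Lists every recording the spec implies -- each human subject performs
#' each of the 21 human movements `human_trials` times, the dummy repeats
#' each of its 4 fall movements `dummy_trials` times -- together with the
#' per-recording RNG seed derived from the master seed. [generate_dataset()]
#' generates exactly these recordings.
#'
#' @param spec An [dataset_spec()] object.
#' @param profiles Profile table (overrides already applied).
#' @return Manifest data frame with columns `recording_id`,
#'   `movement_code`, `category`, `performer`, `subject_id`, `trial_index`,
#'   `seed`.
#' @export
dataset_manifest <- function(spec, profiles = default_profiles()) {
  stopifnot(inherits(spec, "ffh_dataset_spec"))
  rows <- list()
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    if (p$performer == "human") {
      subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
      trials <- seq_len(spec$human_trials)
    } else {
      subjects <- "D01"
      trials <- seq_len(spec$dummy_trials)
    }
    for (s in subjects) {
      for (tr in trials) {
        rows[[length(rows) + 1L]] <- data.frame(
          recording_id = recording_id(p$code, s, tr),
          movement_code = p$code, category = p$category,
          performer = p$performer, subject_id = s, trial_index = tr,
          seed = derive_seed(spec$master_seed, p$code, s, tr),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  manifest
}

#' Generate a full labelled dataset of synthetic recordings
#'
#' Human movements (all NF, all LF and the 0.7 m forward fall) are performed
#' by each synthetic subject `human_trials` times; dummy movements (falls
#' from 2 m and 3 m) are repeated `dummy_trials` times by a single dummy.
#' With the defaults this yields 20 x 21 x 3 = 1260 human and 4 x 5 = 20
#' dummy recordings.
#'
#' @param spec An [dataset_spec()] object.
#' @param profiles Profile table, by default [default_profiles()] with the
#'   spec's overrides applied.
#' @return An `ffh_dataset`: list with `recordings` (named list of
#'   `ffh_recording`) and `manifest` (data frame with columns
#'   `recording_id`, `movement_code`, `category`, `performer`, `subject_id`,
#'   `trial_index`, `seed`).
#' @export
generate_dataset <- function(spec, profiles = default_profiles()) {
  stopifnot(inherits(spec, "ffh_dataset_spec"))
  profiles <- apply_overrides(profiles, spec$overrides)
  manifest <- dataset_manifest(spec, profiles)
  recordings <- vector("list", nrow(manifest))
  names(recordings) <- manifest$recording_id
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    recordings[[i]] <- generate_recording(
      profiles[profiles$code == m$movement_code, ],
      m$subject_id, m$trial_index, m$seed
    )
  }
  structure(list(recordings = recordings, manifest = manifest),
            class = "ffh_dataset")
}

#' Write / read a dataset as CSV files plus a manifest
#'
#' One CSV per recording (columns `time_s`, `acc_x_g`, `acc_y_g`, `acc_z_g`,
#' `gyro_x_dps`, `gyro_y_dps`, `gyro_z_dps`) and a `manifest.csv` listing
#' every recording with its movement code, category, performer, subject,
#' trial and seed. Writing is deterministic: equal datasets produce
#' byte-identical files.
#'
#' @param dataset An `ffh_dataset`.
#' @param dir Output directory (created if missing).
#' @return `write_dataset` invisibly returns the manifest (with a `path`
#'   column); `read_dataset` returns an `ffh_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ffh_dataset"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  rec_dir <- file.path(dir, "recordings")
  dir.create(rec_dir, showWarnings = FALSE)
  manifest <- dataset$manifest
  manifest$path <- file.path("recordings", paste0(manifest$recording_id, ".csv"))
  for (i in seq_len(nrow(manifest))) {
    data.table::fwrite(dataset$recordings[[manifest$recording_id[i]]]$data,
                       file.path(dir, manifest$path[i]))
  }
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv found under: ", dir)
  manifest <- as.data.frame(data.table::fread(mf))
  recordings <- vector("list", nrow(manifest))
  names(recordings) <- manifest$recording_id
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    data <- as.data.frame(data.table::fread(file.path(dir, m$path)))
    recordings[[i]] <- structure(
      list(data = data, sampling_rate = 100,
           movement_code = m$movement_code, category = m$category,
           performer = m$performer, subject_id = m$subject_id,
           trial_index = m$trial_index, seed = m$seed,
           drawn_peak_g = NA_real_),
      class = "ffh_recording"
    )
  }
  structure(list(recordings = recordings,
                 manifest = manifest[, setdiff(names(manifest), "path")]),
            class = "ffh_dataset")
}
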