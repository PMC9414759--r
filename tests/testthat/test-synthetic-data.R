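test_that("default profile table covers the 25 movements with valid calibration", {
  p <- default_profiles()
  expect_equal(nrow(p), 25L)
  expect_equal(sum(p$category == "NF"), 15L)
  expect_equal(sum(p$category == "LF"), 5L)
  expect_equal(sum(p$category == "HF"), 5L)
  expect_setequal(p$code[p$performer == "dummy"],
                  c("HF01", "HF02", "HF04", "HF05"))
  expect_true(all(p$peak_min <= p$peak_mean & p$peak_mean <= p$peak_max))
  expect_true(all(p$peak_sd > 0))
  expect_true(all(p$peak_min[p$category == "HF"] >= 9))
  nf <- p[p$category == "NF" & p$code != "NF15", ]
  expect_true(all(nf$peak_max <= 4))
  nf15 <- p[p$code == "NF15", ]
  expect_true(nf15$peak_min >= 5 && nf15$peak_max <= 9)
  expect_true(all(xor(p$fall_height > 0, !p$has_free_fall)))
  # forward fall carries a larger mean impact than a vertical fall of equal height
  expect_gt(p["HF04", "peak_mean"], p["HF01", "peak_mean"])
  expect_gt(p["HF05", "peak_mean"], p["HF02", "peak_mean"])
})

test_that("recordings are deterministic, finite and windowable", {
  prof <- get_profile("NF02")
  r1 <- generate_recording(prof, "S01", 1, seed = 7)
  r2 <- generate_recording(prof, "S01", 1, seed = 7)
  expect_identical(r1, r2)
  r3 <- generate_recording(prof, "S01", 1, seed = 8)
  expect_false(identical(r1$data, r3$data))

  expect_gte(nrow(r1$data), 100L)
  expect_true(all(is.finite(as.matrix(r1$data))))
  pk <- find_peak(r1)
  expect_gte(pk$peak_index - 1L, 70L)          # window always extractable
  expect_true(pk$peak_value_g >= 1 && pk$peak_value_g <= 4)
})

test_that("invalid seeds and profile fields are rejected by name", {
  prof <- get_profile("NF01")
  expect_error(generate_recording(prof, "S01", 1, seed = "a"), "seed")
  expect_error(generate_recording(prof, "S01", 1, seed = 1.5), "seed")
  bad <- prof
  bad$peak_sd <- NaN
  expect_error(generate_recording(bad, "S01", 1, seed = 1), "peak_sd")
})

test_that("falls from height carry a free-fall phase matching sqrt(2h/g)", {
  rec <- generate_recording(get_profile("HF02"), "D01", 1, seed = 42)
  expect_gte(find_peak(rec)$peak_value_g, 9)
  expect_equal(measured_freefall_s(rec), sqrt(2 * 3 / 9.81), tolerance = 0.2)

  rec2 <- generate_recording(get_profile("HF01"), "D01", 2, seed = 43)
  expect_equal(measured_freefall_s(rec2), sqrt(2 * 2 / 9.81), tolerance = 0.2)
})

test_that("measured peaks stay inside the profile bounds across many draws", {
  profiles <- default_profiles()
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    peaks <- vapply(1:200, function(k) {
      find_peak(generate_recording(prof, "S01", k, seed = 10000 + k))$peak_value_g
    }, numeric(1))
    expect_true(all(peaks >= prof$peak_min - 1e-9 & peaks <= prof$peak_max + 1e-9),
                info = prof$code)
  }
})

test_that("dataset counts follow the subjects-by-movements-by-trials design", {
  spec <- dataset_spec(n_subjects = 2, human_trials = 1, dummy_trials = 1,
                       master_seed = 3)
  ds <- generate_dataset(spec)
  expect_equal(sum(ds$manifest$performer == "human"), 2 * 21 * 1)
  expect_equal(sum(ds$manifest$performer == "dummy"), 4 * 1)
  expect_equal(length(ds$recordings), 46L)

  # default design: 20 x 21 x 3 human + 4 x 5 dummy (manifest only)
  mf <- dataset_manifest(dataset_spec())
  expect_equal(sum(mf$performer == "human"), 1260L)
  expect_equal(sum(mf$performer == "dummy"), 20L)
  expect_false(any(duplicated(mf$recording_id)))

  expect_error(dataset_spec(n_subjects = 0), "n_subjects")
  expect_error(dataset_spec(human_trials = 0), "human_trials")
})

test_that("equal master seeds reproduce identical manifests and CSV bytes", {
  spec <- dataset_spec(n_subjects = 1, human_trials = 1, dummy_trials = 1,
                       master_seed = 99)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$recordings, d2$recordings)

  t1 <- withr::local_tempdir()
  t2 <- withr::local_tempdir()
  write_dataset(d1, t1)
  write_dataset(d2, t2)
  f1 <- list.files(t1, recursive = TRUE)
  expect_identical(f1, list.files(t2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(t1, f), "raw", 1e7),
                     readBin(file.path(t2, f), "raw", 1e7), label = f)
  }
})

test_that("written datasets read back with identical signals and labels", {
  spec <- dataset_spec(n_subjects = 1, human_trials = 1, dummy_trials = 2,
                       master_seed = 5)
  ds <- generate_dataset(spec)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(length(back$recordings), length(ds$recordings))
  id <- ds$manifest$recording_id[10]
  expect_equal(back$recordings[[id]]$data, ds$recordings[[id]]$data,
               tolerance = 1e-12)
  expect_equal(back$recordings[[id]]$movement_code,
               ds$recordings[[id]]$movement_code)
})

test_that("profile overrides reshape the peak distribution and are validated", {
  spec <- dataset_spec(n_subjects = 1, human_trials = 2,
                       overrides = list(NF01 = list(peak_mean = 3.5,
                                                    peak_sd = 0.1)))
  ds <- generate_dataset(spec)
  nf01 <- ds$manifest$recording_id[ds$manifest$movement_code == "NF01"]
  pk <- vapply(ds$recordings[nf01],
               function(r) find_peak(r)$peak_value_g, numeric(1))
  expect_true(all(pk > 2.5))
  expect_error(
    generate_dataset(dataset_spec(overrides = list(HF01 = list(peak_min = 2)))),
    "peak_min"
  )
  expect_error(
    generate_dataset(dataset_spec(overrides = list(ZZ99 = list(peak_mean = 2)))),
    "unknown movement code"
  )
})

test_that("categories separate around the 9 g hazard threshold", {
  profiles <- default_profiles()
  mean_peak <- function(code) {
    prof <- profiles[profiles$code == code, ]
    mean(vapply(1:30, function(k) {
      find_peak(generate_recording(prof, "S01", k, seed = 500 + k))$peak_value_g
    }, numeric(1)))
  }
  hf <- vapply(c("HF01", "HF03", "HF05"), mean_peak, numeric(1))
  nf <- vapply(c("NF01", "NF05", "NF09"), mean_peak, numeric(1))
  expect_true(all(hf > 9))
  expect_true(all(nf < 9))
})
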