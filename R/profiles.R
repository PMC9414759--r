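#' Movement profiles for the synthetic IMU generator
#'
#' The generator covers 25 movement types routinely monitored on construction
#' sites: 15 non-fall working movements (`NF01`--`NF15`), 5 low-hazard
#' ground-level falls (`LF01`--`LF05`: trips, slips, fainting) and 5
#' high-hazard falls from height (`HF01`--`HF05`). A profile fixes, per
#' movement, the distribution of the impact peak acceleration (truncated
#' normal, in g), the fall height (m) driving the free-fall phase, the
#' characteristic angular-velocity scale (deg/s) and the performer: falls from
#' 2 m and above are performed by an anthropomorphic dummy, everything else by
#' human subjects.
#'
#' Peak calibration encodes the observed per-category ranges: ordinary work
#' movements peak at 1--4 g (the 0.7 m jump `NF15` at 5--9 g), low-hazard
#' falls mostly at 4--9 g with the forward/backward slips `LF03`/`LF04`
#' exceeding 10 g, and falls from height at 9 g or more. At equal fall height
#' a forward fall carries a larger mean peak than a vertical (feet-first)
#' fall, which dissipates part of the impact through the legs.
#'
#' @return A data frame with one row per movement and columns `code`,
#'   `label`, `category` (`NF`/`LF`/`HF`), `performer` (`human`/`dummy`),
#'   `peak_mean`, `peak_sd`, `peak_min`, `peak_max` (g), `fall_height` (m),
#'   `has_free_fall`, `gyro_intensity` (deg/s) and `activity_freq` (Hz), the
#'   movement's characteristic oscillation frequency.
#' @examples
#' p <- default_profiles()
#' nrow(p)                       # 25
#' p[p$code == "HF01", "performer"]
#' @export
default_profiles <- function() {
  row <- function(code, label, category, performer, mean, sd, lo, hi,
                  height, gyro, freq) {
    data.frame(
      code = code, label = label, category = category, performer = performer,
      peak_mean = mean, peak_sd = sd, peak_min = lo, peak_max = hi,
      fall_height = height, has_free_fall = height > 0,
      gyro_intensity = gyro, activity_freq = freq,
      stringsAsFactors = FALSE
    )
  }
  profiles <- rbind(
    row("NF01", "Sitting quickly and getting up",      "NF", "human", 2.6, 0.45, 1, 4, 0,   40, 1.1),
    row("NF02", "Sitting and getting up comfortably",  "NF", "human", 1.8, 0.35, 1, 4, 0,   25, 0.8),
    row("NF03", "Going up and down the stairs",        "NF", "human", 2.4, 0.40, 1, 4, 0,   60, 1.8),
    row("NF04", "Going up and down a ladder",          "NF", "human", 2.2, 0.40, 1, 4, 0,   50, 1.4),
    row("NF05", "Working with a pickaxe",              "NF", "human", 3.0, 0.45, 1, 4, 0,   90, 1.0),
    row("NF06", "Lifting (front)",                     "NF", "human", 2.1, 0.40, 1, 4, 0,   45, 0.7),
    row("NF07", "Lifting (back)",                      "NF", "human", 2.3, 0.40, 1, 4, 0,   45, 0.75),
    row("NF08", "Lifting (side)",                      "NF", "human", 2.2, 0.40, 1, 4, 0,   55, 0.85),
    row("NF09", "Moving up and down in an elevator",   "NF", "human", 1.5, 0.25, 1, 4, 0,   15, 0.5),
    row("NF10", "Walking on a beam",                   "NF", "human", 2.0, 0.35, 1, 4, 0,   35, 2.0),
    row("NF11", "Walking on a beam with luggage",      "NF", "human", 2.2, 0.35, 1, 4, 0,   40, 1.9),
    row("NF12", "Shoveling",                           "NF", "human", 2.7, 0.45, 1, 4, 0,   80, 0.9),
    row("NF13", "Stretching",                          "NF", "human", 1.6, 0.30, 1, 4, 0,   30, 0.6),
    row("NF14", "Climbing up and down a scaffold",     "NF", "human", 2.5, 0.40, 1, 4, 0,   65, 2.2),
    row("NF15", "0.7 m jump",                          "NF", "human", 6.5, 0.90, 5, 9, 0.7, 70, 2.6),
    row("LF01", "Forward trip",                        "LF", "human", 6.3, 1.00, 4, 9, 0,  300, 3.0),
    row("LF02", "Lateral trip",                        "LF", "human", 6.0, 1.00, 4, 9, 0,  280, 3.2),
    row("LF03", "Forward slip",                        "LF", "human", 11.5, 0.70, 10, 13, 0, 340, 3.6),
    row("LF04", "Backward slip",                       "LF", "human", 11.4, 0.70, 10, 13, 0, 320, 3.8),
    row("LF05", "Fainting",                            "LF", "human", 6.6, 1.00, 4, 9, 0,  120, 0.4),
    row("HF01", "2 m vertical fall from height",       "HF", "dummy", 10.5, 0.90, 9, 13, 2,  40, 1.2),
    row("HF02", "3 m vertical fall from height",       "HF", "dummy", 11.5, 1.00, 9, 14, 3,  45, 1.3),
    row("HF03", "0.7 m forward fall from height",      "HF", "human", 10.0, 0.80, 9, 13, 0.7, 330, 2.9),
    row("HF04", "2 m forward fall from height",        "HF", "dummy", 12.5, 1.10, 9, 15, 2, 350, 1.6),
    row("HF05", "3 m forward fall from height",        "HF", "dummy", 13.5, 1.20, 9, 16, 3, 360, 1.7)
  )
  rownames(profiles) <- profiles$code
  for (i in seq_len(nrow(profiles))) validate_profile(profiles[i, ])
  profiles
}

#' Fetch one movement profile by code
#'
#' @param code Movement code, e.g. `"HF02"`.
#' @param profiles Profile table, by default [default_profiles()].
#' @return A one-row data frame (see [default_profiles()]).
#' @export
get_profile <- function(code, profiles = default_profiles()) {
  if (!is_string(code) || !code %in% profiles$code) {
    stop("unknown movement code: ", deparse(code))
  }
  profiles[profiles$code == code, , drop = FALSE]
}

# Profile invariants: bound ordering, category peak ranges, performer
# assignment (dummy exactly for the >= 2 m falls), free-fall consistency.
validate_profile <- function(p) {
  for (f in c("peak_mean", "peak_sd", "peak_min", "peak_max", "fall_height",
              "gyro_intensity", "activity_freq")) {
    stopifnot_scalar_finite(p[[f]], f)
  }
  if (p$peak_sd <= 0) stop("field 'peak_sd' must be positive for ", p$code)
  if (!(p$peak_min <= p$peak_mean && p$peak_mean <= p$peak_max)) {
    stop("field 'peak_mean' must lie within [peak_min, peak_max] for ", p$code)
  }
  if (!p$category %in% c("NF", "LF", "HF")) {
    stop("field 'category' must be NF, LF or HF for ", p$code)
  }
  if (p$category == "HF" && p$peak_min < 9) {
    stop("field 'peak_min' must be >= 9 g for HF movement ", p$code)
  }
  if (p$category == "NF" && p$code != "NF15" && p$peak_max > 4) {
    stop("field 'peak_max' must be <= 4 g for NF movement ", p$code)
  }
  if (p$code == "NF15" && (p$peak_min < 5 || p$peak_max > 9)) {
    stop("peak bounds for NF15 must lie within [5, 9] g")
  }
  dummy_codes <- c("HF01", "HF02", "HF04", "HF05")
  if (p$code %in% dummy_codes && p$performer != "dummy") {
    stop("field 'performer' must be 'dummy' for ", p$code)
  }
  if (!p$code %in% dummy_codes && p$performer != "human") {
    stop("field 'performer' must be 'human' for ", p$code)
  }
  if (xor(p$fall_height > 0, p$has_free_fall)) {
    stop("field 'fall_height' must be positive iff 'has_free_fall' for ", p$code)
  }
  invisible(p)
}
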