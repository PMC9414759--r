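# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != trunc(seed)) {
    stop("seed must be a single finite integer, got: ", deparse(seed))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic string hash onto [0, 2^31 - 2]; used to derive one independent
# RNG substream per recording so generation is insertion-order independent.
# Polynomial rolling hash mod the Mersenne prime 2^31 - 1 (all intermediates
# stay below 2^53, so double arithmetic is exact).
hash_string <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 2147483647
  }
  h
}

derive_seed <- function(master_seed, ...) {
  key <- paste(c(...), collapse = "|")
  as.integer((hash_string(key) + as.numeric(master_seed)) %% 2147483647)
}

# Single draw from a normal truncated to [lo, hi] via inverse-CDF; one RNG
# draw, so the stream advances the same amount for every movement profile.
rtrunc_norm1 <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(1L, plo, phi)
  x <- stats::qnorm(u, mean, sd)
  min(max(x, lo), hi)
}

stopifnot_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("field '", name, "' must be a single finite number")
  }
  invisible(x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
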