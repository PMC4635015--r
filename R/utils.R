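# Internal helpers shared across modules.

# 140 simulation units == 30 mm, the only scale consistent with all of the
# stated container sizes (30x60 mm -> 140x280 units, 45 mm radius -> 210).
MM_PER_UNIT <- 3 / 14
UNITS_PER_MM <- 14 / 3

mm_to_units <- function(x) x * UNITS_PER_MM
units_to_mm <- function(x) x * MM_PER_UNIT

# Signed angular difference a - b wrapped to (-pi, pi].
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Bearing convention: 0 points along +y, increasing clockwise, so a bearing
# theta corresponds to the unit step (sin theta, cos theta).
bearing_of <- function(dx, dy) atan2(dx, dy) %% (2 * pi)

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive reproducible sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_wigwag <- function(...) stop(..., call. = FALSE)
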