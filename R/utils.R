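# Internal helpers shared across modules.
#
# Index convention: every sample index stored in a user-facing table or result
# is 0-based (matching the annotation CSV dialect); signal vectors are ordinary
# R vectors, so access is x[idx + 1L]. Conversions between ms and samples use
# base round(), i.e. round-half-to-even, which makes the 35/65 cycle split tile
# exactly for every integer RR.

ms_to_samples <- function(ms, fs) as.integer(round(ms * fs / 1000))

samples_to_ms <- function(n, fs) n * 1000 / fs

#' @keywords internal
#' @noRd
assert_scalar_numeric <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so the generator never disturbs user code.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Strict three-point local extrema with plateau resolution: runs of equal
# values are collapsed and, when a run is lower (higher) than both distinct
# neighbours, the LAST sample of the run is reported. Returns 1-based positions
# into `x`; endpoints are never extrema.
local_extrema <- function(x, kind = c("min", "max")) {
  kind <- match.arg(kind)
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)          # last index of each run
  v <- r$values
  mid <- 2:(k - 1L)
  if (kind == "min") {
    hit <- v[mid] < v[mid - 1L] & v[mid] < v[mid + 1L]
  } else {
    hit <- v[mid] > v[mid - 1L] & v[mid] > v[mid + 1L]
  }
  ends[mid][hit]
}

local_minima <- function(x) local_extrema(x, "min")
local_maxima <- function(x) local_extrema(x, "max")

# Last negative-to-nonnegative crossing of `x`; returns the 1-based position of
# the first nonnegative sample of the crossing, or NA if none.
last_upward_zero_crossing <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_integer_)
  hit <- which(x[-n] < 0 & x[-1L] >= 0)
  if (length(hit) == 0L) return(NA_integer_)
  hit[length(hit)] + 1L
}

# seq of 1-based indices for a half-open window [from, to) already clipped to
# [1, n]; returns integer(0) when empty.
clip_window <- function(from, to, n) {
  from <- max(1L, as.integer(from))
  to <- min(as.integer(to), n + 1L)
  if (from >= to) return(integer(0))
  seq.int(from, to - 1L)
}
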