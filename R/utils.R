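#' @keywords internal
"_PACKAGE"

# Run-length helpers shared by event detection and dive delimitation.
# All event intervals in this package are half-open [start, end) on a
# 1 Hz timeline whose first sample is second 0.

# Maximal runs of TRUE in a logical vector; returns data.frame(start, end)
# with half-open 0-based second indices (start = index of first TRUE - 1).
runs_true <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  if (!any(x)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

# Seconds of [start, end) intervals as an index vector (1-based samples).
interval_samples <- function(start, end) {
  if (end <= start) return(integer(0))
  seq.int(start + 1L, end)
}

# Total seconds of a set of half-open intervals covered by [lo, hi).
overlap_seconds <- function(start, end, lo, hi) {
  pmax(0, pmin(end, hi) - pmax(start, lo))
}

# Linear interpolation that tolerates flagged (NA) samples.
fill_na_linear <- function(x) {
  n <- length(x)
  bad <- is.na(x)
  if (!any(bad)) return(x)
  if (all(bad)) stop("cannot interpolate a fully missing series")
  idx <- seq_len(n)
  stats::approx(idx[!bad], x[!bad], xout = idx, rule = 2)$y
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap degrees to [0, 360).
wrap360 <- function(x) {
  y <- x %% 360
  y[y < 0] <- y[y < 0] + 360
  y[y >= 360] <- 0 # guards -eps %% 360 == 360 in floating point
  y
}

# Cosine-blended ramp from a to b over n samples (smooth first derivative).
smooth_ramp <- function(a, b, n) {
  if (n <= 0) return(numeric(0))
  t <- seq_len(n) / (n + 1)
  a + (b - a) * (1 - cos(pi * t)) / 2
}

# Uniform integer draw in [lo, hi] that is safe when lo == hi.
rint <- function(lo, hi) {
  if (hi <= lo) return(as.integer(lo))
  sample(seq.int(lo, hi), 1L)
}

# Centred moving average with shrinking windows at the edges.
moving_average <- function(x, width) {
  n <- length(x)
  if (width <= 1 || n == 0) return(x)
  half <- floor(width / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
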