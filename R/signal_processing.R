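#' Filter specification
#'
#' Describes a digital Butterworth filter by its physical cutoff(s) and the
#' sampling rate of the series it is meant for. The three filters used by the
#' pipeline are: an order-3 low-pass at 0.20 Hz (static acceleration and
#' magnetometer smoothing), an order-3 high-pass at 2.64 Hz (dynamic
#' acceleration feeding prey-encounter detection), and an order-3 band-pass
#' at 0.44-1.02 Hz (lateral-axis swimming effort). All cutoffs are physical
#' frequencies in Hz at the stated sampling rate.
#'
#' @param kind one of `"lowpass"`, `"highpass"`, `"bandpass"`.
#' @param cutoff_hz one cutoff (low/high-pass) or two increasing cutoffs
#'   (band-pass), strictly inside (0, fs/2).
#' @param fs_hz sampling rate in Hz.
#' @param order filter order (>= 1); the pipeline uses 3 throughout.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass", "bandpass"),
                        cutoff_hz, fs_hz, order = 3L) {
  kind <- match.arg(kind)
  if (order < 1) stop("filter order must be >= 1")
  nc <- if (kind == "bandpass") 2L else 1L
  if (length(cutoff_hz) != nc) {
    stop(sprintf("%s filter needs %d cutoff(s)", kind, nc))
  }
  if (nc == 2L && diff(cutoff_hz) <= 0) stop("band-pass cutoffs must increase")
  nyq <- fs_hz / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq)) {
    stop(sprintf("cutoff(s) %s Hz must lie strictly inside (0, %g) Hz",
                 paste(cutoff_hz, collapse = ", "), nyq))
  }
  structure(list(kind = kind, cutoff_hz = cutoff_hz, fs_hz = fs_hz,
                 order = as.integer(order)),
            class = "filter_spec")
}

#' Design a digital Butterworth filter
#'
#' Bilinear-transform Butterworth design (delegated to [signal::butter()]),
#' returning transfer-function coefficients.
#'
#' @param spec a [filter_spec()].
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
design_butterworth <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  w <- spec$cutoff_hz / (spec$fs_hz / 2) # normalised to Nyquist, as butter()
  type <- switch(spec$kind, lowpass = "low", highpass = "high",
                 bandpass = "pass")
  bt <- signal::butter(spec$order, w, type = type)
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

#' Frequency response magnitude of a designed filter
#'
#' @param spec a [filter_spec()].
#' @param freq_hz frequencies (Hz) at which to evaluate |H(f)|.
#' @return numeric vector of gains.
#' @export
filter_gain <- function(spec, freq_hz) {
  co <- design_butterworth(spec)
  w <- 2 * pi * freq_hz / spec$fs_hz
  z <- exp(1i * w)
  num <- outer(z, seq_along(co$b) - 1, function(zz, k) zz^(-k)) %*% co$b
  den <- outer(z, seq_along(co$a) - 1, function(zz, k) zz^(-k)) %*% co$a
  as.numeric(Mod(num / den))
}

# Odd (point-mirrored) reflection padding, as used by zero-phase filtering.
# Pad length is 3x the filter's characteristic length fs / min cutoff,
# capped at n - 1; flagged seconds at the edges are reported by callers.
pad_length <- function(spec, n) {
  min(n - 1L, as.integer(ceiling(3 * spec$fs_hz / min(spec$cutoff_hz))))
}

filter_one <- function(x, co, spec, mode) {
  n <- length(x)
  np <- pad_length(spec, n)
  pre <- 2 * x[1] - x[seq(np + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - np)]
  xp <- c(pre, x, post)
  y <- signal::filter(co$b, co$a, xp)
  if (mode == "zero_phase") {
    y <- rev(signal::filter(co$b, co$a, rev(y)))
  }
  as.numeric(y[seq(np + 1, np + n)])
}

#' Apply a Butterworth filter to a uniform series
#'
#' Filters each channel of a vector or matrix series. The default
#' `zero_phase` mode filters forward then backward so the output has no group
#' delay, which keeps filtered acceleration states time-aligned with depth
#' and across axes; `forward` gives a single causal pass. Edges are handled
#' by odd-reflection padding of three characteristic filter lengths; the
#' padded edge region is flagged in the `"edge_samples"` attribute.
#'
#' @param x numeric vector or matrix (channels in columns).
#' @param spec a [filter_spec()].
#' @param mode `"zero_phase"` (default) or `"forward"`.
#' @return filtered series, same shape as `x`, with attribute
#'   `"edge_samples"` giving the number of padded samples at each end.
#' @export
apply_filter <- function(x, spec, mode = c("zero_phase", "forward")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "filter_spec"))
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(xm)
  if (n <= 3 * (spec$order + 1)) {
    stop(sprintf("series of length %d too short to filter (need > %d)",
                 n, 3 * (spec$order + 1)))
  }
  co <- design_butterworth(spec)
  ym <- xm
  for (j in seq_len(ncol(xm))) ym[, j] <- filter_one(xm[, j], co, spec, mode)
  out <- if (vec) ym[, 1] else ym
  attr(out, "edge_samples") <- pad_length(spec, n)
  out
}

#' Static (gravitational) acceleration
#'
#' Low-pass filters tri-axial acceleration (order 3, 0.20 Hz) to isolate the
#' gravity component, then rescales each sample to exactly unit norm so that
#' pitch and roll follow from trigonometry alone. Samples whose pre-scaling
#' norm is below `1e-6` g are flagged and replaced by interpolation from
#' their neighbours.
#'
#' @param accel n x 3 matrix of accelerations (g) sampled at `fs_hz`.
#' @param fs_hz sampling rate, default 16 Hz.
#' @param cutoff_hz low-pass cutoff, default 0.20 Hz.
#' @param mode filtering mode passed to [apply_filter()].
#' @return n x 3 matrix with unit row norms; attributes `"flagged"` (indices
#'   of interpolated samples) and `"edge_samples"`.
#' @export
static_acceleration <- function(accel, fs_hz = 16, cutoff_hz = 0.20,
                                mode = "zero_phase") {
  accel <- as.matrix(accel)
  stopifnot(ncol(accel) == 3)
  spec <- filter_spec("lowpass", cutoff_hz, fs_hz)
  low <- apply_filter(accel, spec, mode)
  nrm <- sqrt(rowSums(low^2))
  bad <- which(nrm < 1e-6)
  if (length(bad)) {
    for (j in 1:3) {
      v <- low[, j]
      v[bad] <- NA_real_
      low[, j] <- fill_na_linear(v)
    }
    nrm <- sqrt(rowSums(low^2))
  }
  out <- low / nrm
  attr(out, "flagged") <- bad
  attr(out, "edge_samples") <- attr(low, "edge_samples")
  out
}

#' Dynamic (high-frequency) acceleration
#'
#' High-pass filters tri-axial acceleration (order 3, 2.64 Hz at 16 Hz) to
#' isolate rapid movements such as prey-strike head jerks.
#'
#' @inheritParams static_acceleration
#' @param cutoff_hz high-pass cutoff, default 2.64 Hz.
#' @return filtered matrix (same shape).
#' @export
dynamic_acceleration <- function(accel, fs_hz = 16, cutoff_hz = 2.64,
                                 mode = "zero_phase") {
  accel <- as.matrix(accel)
  spec <- filter_spec("highpass", cutoff_hz, fs_hz)
  apply_filter(accel, spec, mode)
}

# Mean over non-overlapping fs-sample blocks aligned to the record start;
# a trailing partial block is dropped (and noted via attribute).
block_average <- function(x, fs) {
  n <- length(x)
  nb <- n %/% fs
  dropped <- n - nb * fs
  m <- matrix(x[seq_len(nb * fs)], nrow = fs)
  out <- colMeans(m)
  attr(out, "dropped_samples") <- dropped
  out
}

#' Swimming effort at 1 Hz
#'
#' Band-pass filters lateral-axis acceleration to the stroking band
#' (order 3, 0.44-1.02 Hz), rectifies it, and averages over non-overlapping
#' one-second blocks aligned to the record start. The result is a
#' non-negative 1 Hz proxy of stroke-driven locomotion cost; for a pure
#' in-band sinusoid of amplitude A the steady-state value is 2A/pi.
#'
#' @param lateral numeric vector of lateral (sway) acceleration at `fs_hz`.
#' @param fs_hz sampling rate, default 16 Hz.
#' @param band band edges in Hz, default `c(0.44, 1.02)`.
#' @param mode filtering mode passed to [apply_filter()].
#' @return 1 Hz numeric vector of swimming effort.
#' @export
swimming_effort <- function(lateral, fs_hz = 16, band = c(0.44, 1.02),
                            mode = "zero_phase") {
  spec <- filter_spec("bandpass", band, fs_hz)
  y <- apply_filter(as.numeric(lateral), spec, mode)
  block_average(abs(y), fs_hz)
}
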