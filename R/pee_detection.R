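#' Per-second standard deviation of a high-rate signal
#'
#' Sample SD (denominator n-1) over non-overlapping one-second blocks
#' aligned to the record start. A trailing partial block is dropped and
#' reported through the `"dropped_samples"` attribute.
#'
#' @param x numeric vector sampled at `fs` Hz.
#' @param fs samples per block (sampling rate), default 16.
#' @return 1 Hz numeric vector of block SDs.
#' @export
block_sd <- function(x, fs = 16) {
  n <- length(x)
  nb <- n %/% fs
  dropped <- n - nb * fs
  m <- matrix(x[seq_len(nb * fs)], nrow = fs)
  mu <- colMeans(m)
  out <- sqrt(pmax(colSums(m^2) - fs * mu^2, 0) / (fs - 1))
  attr(out, "dropped_samples") <- dropped
  out
}

#' Centred moving standard deviation
#'
#' Sample SD over a centred window (default five seconds at 1 Hz). Edges use
#' the available partial window, never fewer than 3 samples; edge positions
#' are reported in the `"edge_flagged"` attribute.
#'
#' @param x numeric vector at 1 Hz.
#' @param window window width in samples (odd), default 5.
#' @return numeric vector of the same length.
#' @export
moving_sd <- function(x, window = 5L) {
  n <- length(x)
  if (n < 3) stop("moving_sd needs at least 3 samples")
  half <- window %/% 2
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  # widen truncated edge windows to at least 3 samples
  w <- hi - lo + 1L
  lo[w < 3 & lo == 1L] <- 1L
  hi[w < 3 & lo == 1L] <- pmin(3L, n)
  lo[w < 3 & hi == n] <- pmax(n - 2L, 1L)
  w <- hi - lo + 1L
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  out <- sqrt(pmax(s2 - s^2 / w, 0) / (w - 1))
  attr(out, "edge_flagged") <- which(i - half < 1 | i + half > n)
  out
}

#' Exact 1-D two-means clustering
#'
#' Deterministic two-cluster solution in one dimension: the split over the
#' sorted values that minimizes the total within-cluster sum of squares
#' (every 1-D two-means optimum is such a sorted split). The upper cluster
#' is the "high" state. No random initialization is involved. When the two
#' cluster means are not separated by at least `min_separation` pooled
#' within-cluster standard deviations, the input is judged unimodal (no
#' distinct high state) and all values are labelled low with a warning;
#' the same happens when all values are identical.
#'
#' @param values numeric vector (>= 2 values).
#' @param min_separation bimodality guard: required ratio of the
#'   between-cluster mean gap to the pooled within-cluster SD. Set to 0 to
#'   disable the guard.
#' @return list with `threshold` (midpoint between the clusters, or `NA`
#'   when collapsed), `labels` (logical vector, `TRUE` = high state) and
#'   `separation` (the observed ratio).
#' @export
two_means_1d <- function(values, min_separation = 3) {
  n <- length(values)
  if (n < 2) stop("two_means_1d needs at least 2 values")
  if (length(unique(values)) == 1L) {
    warning("all values identical; labelling everything low state")
    return(list(threshold = NA_real_, labels = rep(FALSE, n),
                separation = 0))
  }
  s <- sort(values)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  k <- seq_len(n - 1)
  tot <- cs[n]; tot2 <- cs2[n]
  wss_lo <- cs2[k] - cs[k]^2 / k
  wss_hi <- (tot2 - cs2[k]) - (tot - cs[k])^2 / (n - k)
  wss <- wss_lo + wss_hi
  kbest <- which.min(wss)
  m_lo <- cs[kbest] / kbest
  m_hi <- (tot - cs[kbest]) / (n - kbest)
  pooled <- sqrt(max(wss[kbest], 0) / max(n - 2, 1))
  sep <- if (pooled > 0) (m_hi - m_lo) / pooled else Inf
  if (min_separation > 0 && sep < min_separation) {
    warning(sprintf(
      "two-means separation %.2f below %.2f; no distinct high state",
      sep, min_separation))
    return(list(threshold = NA_real_, labels = rep(FALSE, n),
                separation = sep))
  }
  thr <- (s[kbest] + s[kbest + 1]) / 2
  list(threshold = thr, labels = values > thr, separation = sep)
}

#' Detect prey-encounter events from tri-axial acceleration
#'
#' Full detection pipeline: per-axis dynamic acceleration (order-3 high-pass
#' at 2.64 Hz), per-second block SD, five-second moving SD, exact per-axis
#' two-means state clustering over the whole record, then seconds where all
#' three axes are simultaneously in the high state; maximal runs of such
#' seconds are merged into single events on the 1 Hz state timeline.
#' Clustering is performed once per axis over the whole deployment so that
#' states are comparable across dives.
#'
#' @param accel n x 3 acceleration matrix (g) at `fs_hz`.
#' @param fs_hz sampling rate, default 16.
#' @param min_separation bimodality guard passed to [two_means_1d()].
#' @param mode filtering mode passed to [dynamic_acceleration()].
#' @return data.frame of events with columns `start_s`, `end_s` (half-open
#'   whole seconds) and `duration_s`; attribute `"states"` holds the 1 Hz
#'   per-axis high-state matrix.
#' @export
detect_pee <- function(accel, fs_hz = 16, min_separation = 3,
                       mode = "zero_phase") {
  accel <- as.matrix(accel)
  stopifnot(ncol(accel) == 3)
  if (nrow(accel) < 60 * fs_hz) {
    stop("detection needs a tri-axial record covering at least 60 s")
  }
  dyn <- dynamic_acceleration(accel, fs_hz, mode = mode)
  nsec <- nrow(accel) %/% fs_hz
  states <- matrix(FALSE, nsec, 3)
  for (ax in 1:3) {
    v <- moving_sd(as.numeric(block_sd(dyn[, ax], fs_hz)))
    if (stats::sd(accel[, ax]) == 0) {
      warning(sprintf("axis %d is constant; labelling it all-low", ax))
      next
    }
    states[, ax] <- two_means_1d(as.numeric(v), min_separation)$labels
  }
  ev <- runs_true(states[, 1] & states[, 2] & states[, 3])
  ev$duration_s <- ev$end - ev$start
  names(ev) <- c("start_s", "end_s", "duration_s")
  attr(ev, "states") <- states
  ev
}

#' Assign events to dive phases
#'
#' An event belongs to the phase containing its midpoint second; events
#' whose midpoint falls outside any dive are labelled `"surface"`.
#'
#' @param events data.frame with `start_s`, `end_s` (half-open seconds).
#' @param phases data.frame with `dive`, `phase`, `start_s`, `end_s`.
#' @return `events` with added columns `phase` and `dive` (`NA` outside
#'   dives).
#' @export
assign_events_to_phases <- function(events, phases) {
  n <- nrow(events)
  events$phase <- rep("surface", n)
  events$dive <- rep(NA_integer_, n)
  if (!n || !nrow(phases)) return(events)
  mid <- (events$start_s + events$end_s) / 2
  for (i in seq_len(n)) {
    j <- which(phases$start_s <= mid[i] & mid[i] < phases$end_s)
    if (length(j)) {
      events$phase[i] <- phases$phase[j[1]]
      events$dive[i] <- phases$dive[j[1]]
    }
  }
  events
}
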