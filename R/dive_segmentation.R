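#' Zero offset correction of a depth record
#'
#' Removes slow pressure-sensor baseline drift so surface readings centre on
#' zero. Per rolling window (default 3 h) the baseline is the 10th
#' percentile of raw samples shallower than `surface_max_m`; baselines are
#' anchored at window midpoints and linearly interpolated between them
#' (carried forward, with a warning, over windows that contain no
#' near-surface samples). The corrected depth is clipped at -0.5 m, the
#' sensor resolution.
#'
#' @param depth 1 Hz depth vector (m).
#' @param window_s rolling window length (s), default 3 h.
#' @param surface_max_m raw depth below which samples count as near-surface.
#' @param quantile_p baseline quantile, default 0.10.
#' @return list with `depth` (corrected) and `offset` (the subtracted
#'   baseline series).
#' @export
zero_offset_correct <- function(depth, window_s = 3 * 3600,
                                surface_max_m = 10, quantile_p = 0.10) {
  n <- length(depth)
  starts <- seq(1, n, by = window_s)
  mids <- pmin(starts + window_s / 2, n)
  base <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(starts[i] + window_s - 1, n)
    sel <- idx[depth[idx] < surface_max_m]
    if (length(sel)) {
      b <- stats::quantile(depth[sel], quantile_p, names = FALSE)
      base[i] <- b
      # anchor the baseline at the times that realize the low quantile, so
      # a steady drift is tracked without the half-window lag bias
      at <- sel[abs(depth[sel] - b) <= 0.5]
      if (length(at)) mids[i] <- mean(at)
    }
  }
  ord <- order(mids)
  mids <- mids[ord]; base <- base[ord]
  if (all(is.na(base))) {
    warning("no near-surface samples anywhere; depth returned uncorrected")
    return(list(depth = depth, offset = rep(0, n)))
  }
  if (any(is.na(base))) {
    warning("window(s) without near-surface samples; baseline carried over")
    base <- fill_na_linear(base)
  }
  offset <- if (length(base) == 1L) rep(base, n) else {
    o <- stats::approx(mids, base, xout = seq_len(n), rule = 2,
                       ties = mean)$y
    # extrapolate linearly beyond the first/last anchors so a steady drift
    # is tracked right to the record edges
    k <- length(mids)
    s1 <- (base[2] - base[1]) / (mids[2] - mids[1])
    sk <- (base[k] - base[k - 1]) / (mids[k] - mids[k - 1])
    i <- seq_len(n)
    o[i < mids[1]] <- base[1] + s1 * (i[i < mids[1]] - mids[1])
    o[i > mids[k]] <- base[k] + sk * (i[i > mids[k]] - mids[k])
    o
  }
  list(depth = pmax(depth - offset, -0.5), offset = offset)
}

#' Delimit dives in a corrected depth record
#'
#' Dives are maximal runs of depth strictly greater than `threshold_m`
#' (15 m). Duration bounds (500-1950 s) are applied as exclusion flags:
#' out-of-bounds dives are kept in the output for audit with
#' `excluded = "too_short"` or `"too_long"`, never silently dropped.
#'
#' @param depth corrected 1 Hz depth vector.
#' @param threshold_m dive depth threshold (m), default 15.
#' @param min_duration_s,max_duration_s admissible dive duration bounds (s).
#' @return data.frame with `dive`, `start_s`, `end_s` (half-open seconds),
#'   `duration_s`, `max_depth_m`, `excluded` (`"none"`, `"too_short"`,
#'   `"too_long"`).
#' @export
detect_dives <- function(depth, threshold_m = 15,
                         min_duration_s = 500, max_duration_s = 1950) {
  r <- runs_true(depth > threshold_m)
  if (!nrow(r)) {
    return(data.frame(dive = integer(0), start_s = integer(0),
                      end_s = integer(0), duration_s = integer(0),
                      max_depth_m = numeric(0), excluded = character(0)))
  }
  dur <- r$end - r$start
  maxd <- vapply(seq_len(nrow(r)), function(i) {
    max(depth[interval_samples(r$start[i], r$end[i])])
  }, numeric(1))
  excl <- rep("none", nrow(r))
  excl[dur < min_duration_s] <- "too_short"
  excl[dur > max_duration_s] <- "too_long"
  data.frame(dive = seq_len(nrow(r)), start_s = r$start, end_s = r$end,
             duration_s = dur, max_depth_m = maxd, excluded = excl)
}

#' Smoothed vertical speed within a dive
#'
#' Central finite difference of the 3-s moving-average-smoothed depth;
#' descending (depth increasing) is positive. One-sided differences at the
#' segment ends. The smoothing suppresses the 0.5 m/s spikes that the 0.5 m
#' depth quantization would otherwise inject.
#'
#' @param depth 1 Hz depth segment of one dive (m).
#' @param smooth_s moving-average width (s), default 3.
#' @return signed speed (m/s), same length as `depth`.
#' @export
vertical_speed <- function(depth, smooth_s = 3L) {
  n <- length(depth)
  d <- moving_average(depth, smooth_s)
  if (n < 3) return(rep(0, n))
  v <- numeric(n)
  v[2:(n - 1)] <- (d[3:n] - d[1:(n - 2)]) / 2
  v[1] <- d[2] - d[1]
  v[n] <- d[n] - d[n - 1]
  v
}

#' Find wiggles and steps in a dive profile
#'
#' Operational definitions on the smoothed vertical speed `v` (descending
#' positive): a *wiggle* is a down-then-up excursion — an ascending
#' (`v < 0`) run that is preceded by a descending sample and followed by a
#' return to descending before the end of the dive; its interval runs from
#' the local depth maximum (the last descending sample before the ascent)
#' to the end of the ascending run, half-open. The terminal ascent of the
#' dive (no later descending sample) is never a wiggle. A *step* is a
#' maximal run of at least `min_step_s` seconds with `v` strictly inside
#' (0, `step_max_speed`) m/s; samples already covered by a wiggle are
#' excluded first (overlaps resolve in favour of the wiggle).
#'
#' @param depth 1 Hz depth segment of one dive.
#' @param step_max_speed step vertical-speed ceiling (m/s), default 0.35.
#' @param min_step_s minimum step duration (s), default 5.
#' @param min_wiggle_amp_m minimum depth range of a wiggle (m), default 0
#'   (any sign change counts).
#' @param smooth_s speed smoothing passed to [vertical_speed()].
#' @return data.frame with `kind` (`"wiggle"`/`"step"`), `start_s`, `end_s`
#'   (half-open seconds relative to the segment start), `min_depth_m`,
#'   `max_depth_m`.
#' @export
find_wiggles_steps <- function(depth, step_max_speed = 0.35, min_step_s = 5L,
                               min_wiggle_amp_m = 0, smooth_s = 3L) {
  n <- length(depth)
  v <- vertical_speed(depth, smooth_s)
  v[abs(v) < 1e-9] <- 0 # numerical deadband: treat fp dust as level swimming
  out <- data.frame(kind = character(0), start_s = integer(0),
                    end_s = integer(0), min_depth_m = numeric(0),
                    max_depth_m = numeric(0))
  if (n < 4) return(out)

  asc <- runs_true(v < 0)
  desc_idx <- which(v > 0)
  wig_mask <- rep(FALSE, n)
  for (i in seq_len(nrow(asc))) {
    a0 <- asc$start[i]; a1 <- asc$end[i] # half-open [a0, a1)
    # a wiggle needs descent somewhere before its ascending limb, and must
    # end inside the dive: the run reaching the final sample is the
    # terminal ascent, not a wiggle
    if (!any(desc_idx <= a0) || a1 >= n) next
    seg <- a0:a1 # 1-based: boundary sample a0 is the local depth maximum
    if (diff(range(depth[seg])) < min_wiggle_amp_m) next
    out <- rbind(out, data.frame(kind = "wiggle", start_s = a0,
                                 end_s = a1,
                                 min_depth_m = min(depth[seg]),
                                 max_depth_m = max(depth[seg])))
    wig_mask[seg] <- TRUE
  }

  st <- runs_true(v > 0 & v < step_max_speed & !wig_mask)
  st <- st[st$end - st$start >= min_step_s, , drop = FALSE]
  for (i in seq_len(nrow(st))) {
    seg <- interval_samples(st$start[i], st$end[i])
    out <- rbind(out, data.frame(kind = "step", start_s = st$start[i],
                                 end_s = st$end[i],
                                 min_depth_m = min(depth[seg]),
                                 max_depth_m = max(depth[seg])))
  }
  out[order(out$start_s), , drop = FALSE]
}

#' Partition a dive into descent, bottom and ascent
#'
#' The bottom phase spans from the start of the first to the end of the
#' last *qualifying* event — a wiggle or step whose maximum depth exceeds
#' `ledge` (75%) of the dive's maximum depth. When no event qualifies, the
#' fallback bottom is the first-to-last crossing of the ledge isobath and
#' the dive is flagged `fallback_delimitation`.
#'
#' @param depth 1 Hz depth segment of one dive.
#' @param events event data.frame from [find_wiggles_steps()] (relative
#'   seconds), possibly empty.
#' @param ledge bottom depth threshold as a fraction of max depth, default
#'   0.75.
#' @return data.frame of three phases (`descent`, `bottom`, `ascent`) with
#'   `start_s`, `end_s` relative to the segment, and attribute
#'   `"fallback"` (logical).
#' @export
delimit_bottom <- function(depth, events, ledge = 0.75) {
  n <- length(depth)
  maxd <- max(depth)
  fallback <- FALSE
  qual <- events[events$max_depth_m > ledge * maxd, , drop = FALSE]
  if (nrow(qual)) {
    b0 <- min(qual$start_s)
    b1 <- max(qual$end_s)
  } else {
    fallback <- TRUE
    deep <- which(depth >= ledge * maxd)
    b0 <- min(deep) - 1L
    b1 <- max(deep)
  }
  b0 <- max(b0, 1L) # keep a non-empty descent
  b1 <- min(b1, n - 1L) # and a non-empty ascent
  ph <- data.frame(phase = c("descent", "bottom", "ascent"),
                   start_s = c(0L, b0, b1),
                   end_s = c(b0, b1, n))
  attr(ph, "fallback") <- fallback
  ph
}

#' Flag drift dives
#'
#' A dive is a drift dive when it contains a passive segment of at least
#' `min_dur_s` (200 s) in which per-second swimming effort stays below the
#' deployment's low-effort threshold (its 10th percentile) while the
#' vertical speed is a stable slow sink or rise: SD below `speed_sd_max`
#' and mean |speed| inside `speed_range` (0.05-0.6 m/s). The thresholds
#' reconstruct the usual drift-dive operational definition; all are
#' arguments.
#'
#' @param depth 1 Hz depth segment of one dive.
#' @param effort 1 Hz swimming effort aligned with `depth`.
#' @param effort_threshold low-effort threshold (deployment 10th percentile
#'   of effort).
#' @param min_dur_s minimum passive segment length (s).
#' @param speed_range admissible mean |vertical speed| range (m/s).
#' @param speed_sd_max maximum SD of |vertical speed| in the segment.
#' @return logical: is this a drift dive?
#' @export
flag_drift_dives <- function(depth, effort, effort_threshold,
                             min_dur_s = 200, speed_range = c(0.05, 0.6),
                             speed_sd_max = 0.1) {
  stopifnot(length(effort) == length(depth))
  v <- abs(vertical_speed(depth))
  cand <- effort < effort_threshold & v > speed_range[1] & v < speed_range[2]
  r <- runs_true(cand)
  r <- r[r$end - r$start >= min_dur_s, , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    av <- v[interval_samples(r$start[i], r$end[i])]
    if (stats::sd(av) < speed_sd_max) return(TRUE)
  }
  FALSE
}

#' Segment a deployment into dives, phases and bottom events
#'
#' Convenience wrapper running the whole segmentation stage: zero offset
#' correction, dive delimitation with duration-bound flags, per-dive
#' wiggle/step detection, three-phase partition and drift-dive flagging.
#'
#' @param depth raw 1 Hz depth vector.
#' @param effort 1 Hz swimming effort for the whole record (for drift
#'   flagging); `NULL` skips drift detection.
#' @param ledge bottom delimitation ledge, default 0.75.
#' @return list with `dives` (including `drift` and `fallback` flags),
#'   `phases` and `events` in absolute record seconds, plus `depth_corrected`.
#' @export
segment_deployment <- function(depth, effort = NULL, ledge = 0.75) {
  zoc <- zero_offset_correct(depth)
  dives <- detect_dives(zoc$depth)
  thr <- if (!is.null(effort)) stats::quantile(effort, 0.10, names = FALSE) else NA
  phases <- data.frame()
  events <- data.frame()
  dives$drift <- logical(nrow(dives))
  dives$fallback <- logical(nrow(dives))
  for (i in seq_len(nrow(dives))) {
    seg <- zoc$depth[interval_samples(dives$start_s[i], dives$end_s[i])]
    ev <- find_wiggles_steps(seg)
    ph <- delimit_bottom(seg, ev, ledge)
    dives$fallback[i] <- attr(ph, "fallback")
    if (!is.null(effort)) {
      eseg <- effort[interval_samples(dives$start_s[i],
                                      min(dives$end_s[i], length(effort)))]
      if (length(eseg) == length(seg)) {
        dives$drift[i] <- flag_drift_dives(seg, eseg, thr)
      }
    }
    ph$dive <- dives$dive[i]
    ph$start_s <- ph$start_s + dives$start_s[i]
    ph$end_s <- ph$end_s + dives$start_s[i]
    phases <- rbind(phases, ph)
    if (nrow(ev)) {
      ev$dive <- dives$dive[i]
      ev$start_s <- ev$start_s + dives$start_s[i]
      ev$end_s <- ev$end_s + dives$start_s[i]
      events <- rbind(events, ev)
    }
  }
  list(dives = dives, phases = phases, events = events,
       depth_corrected = zoc$depth, offset = zoc$offset)
}
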