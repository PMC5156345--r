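#' Simulator configuration
#'
#' Parameters of the synthetic daily-diary deployment generator. Defaults
#' emulate a post-breeding female southern elephant seal record: dives of
#' roughly 500-1950 s (mean 1103 s, SD 308 s) reaching 200-1300 m, separated
#' by 2-3 min surface intervals, lateral-axis stroking at 0.7 Hz inside the
#' 0.44-1.02 Hz swimming band, broadband (3-7.5 Hz) tri-axial bursts marking
#' prey encounters at the bottom, 0.5 m depth quantization, slow
#' pressure-sensor drift, and GPS fixes at 60% of surfacings.
#'
#' @param seed integer RNG seed; identical seed and config give bit-identical
#'   deployments.
#' @param n_dives number of dives (0 gives a pure surface record).
#' @param depth_range_m min/max target maximum dive depth (m).
#' @param dive_duration_s admissible dive duration range (s).
#' @param dive_duration_mean_s,dive_duration_sd_s mean and SD of the
#'   truncated-normal dive duration draw.
#' @param surface_duration_s surface interval range (s).
#' @param swim_speed_m_s constant swim speed along the body axis (m/s). The
#'   true vertical speed is `swim_speed * sin(|pitch|)`.
#' @param stroke_freq_hz stroking frequency, inside \[0.44, 1.02\] Hz.
#' @param stroke_amp lateral stroking amplitude (g).
#' @param pee_per_bottom_min expected prey-encounter burst rate per bottom
#'   minute.
#' @param pee_transit_frac expected transit (descent + ascent) burst count as
#'   a fraction of the bottom burst count, split evenly between phases.
#' @param burst_dur_s burst duration range (s).
#' @param burst_amp burst RMS amplitude at envelope peak (g).
#' @param noise_sd white accelerometer noise SD (g).
#' @param pressure_drift_m_per_h linear pressure-sensor drift rate (m/h).
#' @param gps_fix_prob probability that a surfacing yields a GPS fix.
#' @param mag_field local magnetic field vector in the North-East-Down frame
#'   (arbitrary units; default has the steep negative inclination of the
#'   southern Indian Ocean).
#' @param wiggles_per_dive,wiggle_amp_m count range and amplitude range of
#'   bottom wiggles per dive.
#' @param steps_per_dive,step_speed_m_s,step_dur_s count, vertical-speed and
#'   duration ranges of bottom steps; step speeds must stay below 0.35 m/s.
#' @param n_drift_dives number of passive drift dives inserted at random
#'   positions (no stroking, slow constant sink).
#' @param drift_sink_m_s,drift_dur_s drift-segment sink rate and duration.
#' @param n_two_axis_bursts negative-control bursts injected on the X and Y
#'   axes only (never detectable by the tri-axial coincidence rule).
#' @param bottom_meander_m amplitude of the slow depth meander between bottom
#'   events (m); exercises the 0.5 m quantization realistically.
#' @param heading_walk_sd per-second SD (degrees) of the bottom-phase heading
#'   random walk.
#' @param start_time POSIXct start of the record (UTC).
#' @param start_lat,start_lon deployment start position (decimal degrees).
#' @param individual individual identifier.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_dives = 50L,
                       depth_range_m = c(200, 1300),
                       dive_duration_s = c(600, 1900),
                       dive_duration_mean_s = 1103,
                       dive_duration_sd_s = 308,
                       surface_duration_s = c(120, 180),
                       swim_speed_m_s = 2,
                       stroke_freq_hz = 0.70,
                       stroke_amp = 0.30,
                       pee_per_bottom_min = 0.80,
                       pee_transit_frac = 0.28,
                       burst_dur_s = c(1.5, 4),
                       burst_amp = 0.60,
                       noise_sd = 0.05,
                       pressure_drift_m_per_h = 0.5,
                       gps_fix_prob = 0.6,
                       mag_field = c(18, 0, -45),
                       wiggles_per_dive = c(1L, 4L),
                       wiggle_amp_m = c(8, 30),
                       steps_per_dive = c(0L, 2L),
                       step_speed_m_s = c(0.10, 0.30),
                       step_dur_s = c(20, 60),
                       n_drift_dives = 3L,
                       drift_sink_m_s = 0.28,
                       drift_dur_s = 400,
                       n_two_axis_bursts = 0L,
                       bottom_meander_m = 0.4,
                       heading_walk_sd = 6,
                       start_time = as.POSIXct("2014-11-04 17:00:00", tz = "UTC"),
                       start_lat = -49.3,
                       start_lon = 70.3,
                       individual = "ind01") {
  cfg <- as.list(environment())
  if (any(c(cfg$dive_duration_s, cfg$surface_duration_s, cfg$burst_dur_s,
            cfg$step_dur_s) <= 0)) {
    stop("all durations must be positive")
  }
  if (stroke_freq_hz < 0.44 || stroke_freq_hz > 1.02) {
    stop("stroke_freq_hz must lie inside the 0.44-1.02 Hz swimming band")
  }
  if (any(step_speed_m_s <= 0) || any(step_speed_m_s >= 0.35)) {
    stop("step speeds must lie strictly inside (0, 0.35) m/s")
  }
  # feasibility: deepest requested dive must be reachable within the longest
  # admissible duration at the given swim speed (descent + ascent only)
  if (depth_range_m[2] > swim_speed_m_s * dive_duration_s[2] / 2) {
    stop(sprintf(
      "max depth %g m unreachable: %g s at swim speed %g m/s allows at most %g m",
      depth_range_m[2], dive_duration_s[2], swim_speed_m_s,
      swim_speed_m_s * dive_duration_s[2] / 2))
  }
  structure(cfg, class = "sim_config")
}

# Per-second depth increments for a smooth transit of `drop` metres over
# `n` seconds: trapezoidal speed profile with cosine-blended edges.
transit_increments <- function(drop, n, edge = 10L) {
  edge <- min(edge, floor(n / 3))
  w <- rep(1, n)
  if (edge > 0) {
    t <- seq_len(edge) / (edge + 1)
    w[seq_len(edge)] <- (1 - cos(pi * t)) / 2
    w[n + 1 - seq_len(edge)] <- (1 - cos(pi * t)) / 2
  }
  drop * w / sum(w)
}

#' Simulate one dive profile with event ground truth
#'
#' Builds a 1 Hz depth segment (surface-to-surface, metres, no quantization
#' or drift) containing the requested bottom wiggles and steps, and returns
#' the exact event and phase intervals. Wiggles are smooth down-then-up
#' excursions below the bottom baseline; their truth interval runs from the
#' local depth maximum to the end of the ascending limb, matching the
#' operational definition used by [find_wiggles_steps()]. Steps descend at a
#' constant rate strictly inside (0, 0.35) m/s. Events are laid out in the
#' given order with random gaps; the bottom baseline is placed so the
#' profile's maximum equals `max_depth_m` and all events stay below 75% of
#' it.
#'
#' @param duration_s total dive duration (s).
#' @param max_depth_m maximum dive depth (m).
#' @param wiggle_spec data.frame with columns `amp_m`, `dur_s` (may be empty
#'   or NULL).
#' @param step_spec data.frame with columns `speed_m_s`, `dur_s` (may be
#'   empty or NULL).
#' @param swim_speed_m_s swim speed bound for transit pitch feasibility.
#' @param descent_s,ascent_s transit durations; defaults 28% of the dive
#'   each.
#' @param meander_m slow sinusoidal depth meander amplitude at the bottom.
#' @param drift_segment optional list(speed_m_s, dur_s): replaces bottom
#'   events by a passive constant-rate sink (drift dive).
#' @return list with `depth` (length `duration_s`), `events` (data.frame
#'   kind/start_s/end_s relative to dive start, half-open), `phases`
#'   (descent/bottom/ascent intervals), `max_depth_m`.
#' @export
simulate_dive_profile <- function(duration_s, max_depth_m,
                                  wiggle_spec = NULL, step_spec = NULL,
                                  swim_speed_m_s = 2,
                                  descent_s = NULL, ascent_s = NULL,
                                  meander_m = 0, drift_segment = NULL) {
  T <- as.integer(round(duration_s))
  if (is.null(descent_s)) descent_s <- round(0.28 * T)
  if (is.null(ascent_s)) ascent_s <- round(0.28 * T)
  t_d <- as.integer(descent_s); t_a <- as.integer(ascent_s)
  B <- T - t_d - t_a
  if (B < 20) stop("bottom span too short for the requested transits")
  if (!is.null(step_spec) && nrow(step_spec) &&
      any(step_spec$speed_m_s >= 0.35 | step_spec$speed_m_s <= 0)) {
    stop("step speed >= 0.35 m/s would not be a step")
  }

  if (!is.null(drift_segment)) {
    dd <- min(as.integer(drift_segment$dur_s), B - 10L)
    drop <- drift_segment$speed_m_s * dd
    b0 <- max_depth_m - drop
    inc_b <- c(rep(0, floor((B - dd) / 2)),
               rep(drift_segment$speed_m_s, dd),
               rep(0, B - dd - floor((B - dd) / 2)))
    events <- data.frame(kind = character(0), start_s = integer(0),
                         end_s = integer(0))
    first_ev <- floor((B - dd) / 2); last_ev <- first_ev + dd
  } else {
    wiggle_spec <- if (is.null(wiggle_spec)) {
      data.frame(amp_m = numeric(0), dur_s = numeric(0))
    } else as.data.frame(wiggle_spec)
    step_spec <- if (is.null(step_spec)) {
      data.frame(speed_m_s = numeric(0), dur_s = numeric(0))
    } else as.data.frame(step_spec)
    # guarantee wiggle limb speeds stay below the swim speed
    if (nrow(wiggle_spec)) {
      wiggle_spec$dur_s <- pmax(wiggle_spec$dur_s,
                                ceiling(pi * wiggle_spec$amp_m /
                                          (0.85 * swim_speed_m_s)))
    }
    ev <- rbind(
      if (nrow(wiggle_spec)) data.frame(kind = "wiggle",
                                        dur = as.integer(round(wiggle_spec$dur_s)),
                                        amp = wiggle_spec$amp_m, speed = NA_real_),
      if (nrow(step_spec)) data.frame(kind = "step",
                                      dur = as.integer(round(step_spec$dur_s)),
                                      amp = NA_real_, speed = step_spec$speed_m_s))
    if (is.null(ev)) ev <- data.frame(kind = character(0), dur = integer(0),
                                      amp = numeric(0), speed = numeric(0))
    tot_ev <- sum(ev$dur)
    # drop events until they fit with >= 5 s gaps around each
    while (nrow(ev) &&
           (tot_ev > 0.8 * B || B - tot_ev < 5 * (nrow(ev) + 1))) {
      ev <- ev[-nrow(ev), , drop = FALSE]
      tot_ev <- sum(ev$dur)
    }
    k <- nrow(ev)
    if (k > 1) ev <- ev[sample.int(k), , drop = FALSE]
    # random gaps (>= 5 s at entry/exit) around events
    slack <- B - tot_ev
    g <- if (k) stats::runif(k + 1, 0.2, 1) else 1
    gaps <- floor(5 + (slack - 5 * (k + 1)) * g / sum(g))
    stopifnot(all(gaps >= 0))

    inc_b <- numeric(0)
    events <- data.frame(kind = character(0), start_s = integer(0),
                         end_s = integer(0))
    pos <- 0L
    for (i in seq_len(k)) {
      inc_b <- c(inc_b, rep(0, gaps[i]))
      pos <- pos + gaps[i]
      if (ev$kind[i] == "wiggle") {
        L <- ev$dur[i]
        # raised-cosine bump: smooth entry/exit, local depth max at L/2
        shape <- ev$amp[i] * (1 - cos(2 * pi * seq_len(L) / L)) / 2
        inc <- diff(c(0, shape))
        inc[L] <- inc[L] - shape[L] # return exactly to baseline
        inc_b <- c(inc_b, inc)
        # truth: local depth max (mid-bump) to end of ascending limb
        events <- rbind(events, data.frame(
          kind = "wiggle", start_s = pos + as.integer(floor(L / 2)),
          end_s = pos + L))
      } else {
        L <- ev$dur[i]
        inc <- rep(ev$speed[i], L)
        e <- min(3L, floor(L / 4))
        if (e > 0) { # soft edges, keeping interior speed strictly in (0, s]
          t <- seq_len(e) / (e + 1)
          inc[seq_len(e)] <- ev$speed[i] * t
          inc[L + 1 - seq_len(e)] <- ev$speed[i] * t
        }
        inc_b <- c(inc_b, inc)
        events <- rbind(events, data.frame(kind = "step", start_s = pos,
                                           end_s = pos + L))
      }
      pos <- pos + ev$dur[i]
    }
    inc_b <- c(inc_b, rep(0, B - length(inc_b)))
    if (nrow(events)) {
      first_ev <- min(events$start_s); last_ev <- max(events$end_s)
    } else {
      first_ev <- 0L; last_ev <- B
    }
    rel <- cumsum(inc_b)
    relmax <- if (length(rel)) max(rel) else 0
    b0 <- max_depth_m - relmax - meander_m
  }

  rel_bottom <- cumsum(inc_b)
  if (meander_m > 0 && is.null(drift_segment)) {
    ph <- stats::runif(1, 0, 2 * pi)
    rel_bottom <- rel_bottom + meander_m *
      (sin(2 * pi * 0.03 * seq_len(B) + ph) - sin(ph)) / 2
  }
  depth <- c(cumsum(transit_increments(b0, t_d)),
             b0 + rel_bottom,
             b0 + rel_bottom[B] -
               cumsum(transit_increments(b0 + rel_bottom[B], t_a)))
  depth[T] <- 0
  events$start_s <- events$start_s + t_d
  events$end_s <- events$end_s + t_d
  phases <- data.frame(
    phase = c("descent", "bottom", "ascent"),
    start_s = c(0L, t_d + first_ev, t_d + last_ev),
    end_s = c(t_d + first_ev, t_d + last_ev, T))
  list(depth = depth, events = events, phases = phases,
       max_depth_m = max(depth))
}

#' Prey-encounter burst waveform
#'
#' Band-limited (3-7.5 Hz) noise of `n` samples at 16 Hz, scaled to unit
#' SD and amplitude-modulated by a half-sine envelope; at least 80% of its
#' spectral power lies above the 2.64 Hz detection cutoff. This is the
#' waveform the simulator injects (scaled by `burst_amp`) on all three
#' axes at each prey encounter. Draws from the current RNG stream.
#'
#' @param n number of samples.
#' @param fs sampling rate, default 16 Hz.
#' @return numeric vector of length `n`.
#' @export
burst_waveform <- function(n, fs = 16) {
  spec <- filter_spec("bandpass", c(3, 7.5), fs)
  pad <- 4 * fs
  w <- stats::rnorm(n + 2 * pad)
  y <- apply_filter(w, spec)[pad + seq_len(n)]
  y <- y / max(stats::sd(y), .Machine$double.eps)
  y * sin(pi * seq_len(n) / n)
}

# Place `n` events of the given durations uniformly inside [lo, hi) with
# >= 2 s separation; returns data.frame(start_s, end_s) (fractional seconds).
place_bursts <- function(n, durs, lo, hi) {
  out <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (n <= 0 || hi - lo < max(durs, 3) + 4) return(out)
  starts <- sort(stats::runif(n, lo + 1, hi - max(durs) - 1))
  last_end <- -Inf
  for (i in seq_len(n)) {
    if (starts[i] >= last_end + 2) {
      out <- rbind(out, data.frame(start_s = starts[i],
                                   end_s = starts[i] + durs[i]))
      last_end <- starts[i] + durs[i]
    }
  }
  out
}

#' Simulate a full sensor deployment with ground truth
#'
#' Generates one synthetic daily-diary record: 1 Hz depth (quantized to
#' 0.5 m, then pressure drift added), 16 Hz tri-axial acceleration (gravity
#' projected into the body frame by the true orientation, plus lateral
#' stroking, injected prey-encounter bursts and white noise), 16 Hz
#' tri-axial magnetometry (local field rotated into the body frame), and GPS
#' fixes at a fraction of surfacings. The companion truth object holds dive,
#' phase and event boundaries, injected burst intervals, the true 1 Hz
#' orientation, the true (noiseless, unquantized) depth and the pressure
#' offset series.
#'
#' Sign conventions: body axes X forward, Y right, Z down; a stationary
#' level logger reads (0, 0, +1) g; pitch positive nose-up; heading
#' clockwise from magnetic north (NED frame).
#'
#' @param config a [sim_config()].
#' @return list with elements `deployment` (class `ses_deployment`) and
#'   `truth` (class `ses_truth`).
#' @export
simulate_deployment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  fs <- 16L

  n <- cfg$n_dives
  drift_ids <- if (n > 0 && cfg$n_drift_dives > 0) {
    sort(sample.int(n, min(cfg$n_drift_dives, n)))
  } else integer(0)

  depth <- numeric(0)      # 1 Hz true depth
  strok <- numeric(0)      # stroking amplitude multiplier per second
  head_tgt <- numeric(0)   # heading target per second (deg, unwrapped-ish)
  dives <- data.frame()
  phases <- data.frame()
  events <- data.frame()
  surf_mid <- numeric(0)   # surfacing midpoints (s) for GPS
  dive_span <- data.frame()

  add_surface <- function(dur, hdg) {
    depth <<- c(depth, rep(0, dur))
    strok <<- c(strok, rep(0.5, dur))
    head_tgt <<- c(head_tgt, rep(hdg, dur))
  }

  hdg_prev <- stats::runif(1, 0, 360)
  s0 <- round(stats::runif(1, cfg$surface_duration_s[1], cfg$surface_duration_s[2]))
  surf_mid <- c(surf_mid, s0 / 2)
  add_surface(s0, hdg_prev)

  for (i in seq_len(n)) {
    T <- round(min(max(stats::rnorm(1, cfg$dive_duration_mean_s,
                                    cfg$dive_duration_sd_s),
                       cfg$dive_duration_s[1]), cfg$dive_duration_s[2]))
    bf <- stats::runif(1, 0.32, 0.52)
    B <- round(bf * T)
    a <- stats::runif(1, 0.45, 0.55)
    t_d <- round(a * (T - B)); t_a <- T - B - t_d
    Dmax_feas <- 0.92 * cfg$swim_speed_m_s * min(t_d, t_a)
    D <- min(stats::runif(1, cfg$depth_range_m[1], cfg$depth_range_m[2]),
             Dmax_feas)

    is_drift <- i %in% drift_ids
    if (is_drift) {
      prof <- simulate_dive_profile(
        T, 0.6 * D, swim_speed_m_s = cfg$swim_speed_m_s,
        descent_s = t_d, ascent_s = t_a,
        drift_segment = list(speed_m_s = cfg$drift_sink_m_s,
                             dur_s = min(cfg$drift_dur_s, B - 12)))
    } else {
      kw <- rint(cfg$wiggles_per_dive[1], cfg$wiggles_per_dive[2])
      ks <- rint(cfg$steps_per_dive[1], cfg$steps_per_dive[2])
      wspec <- if (kw > 0) data.frame(
        amp_m = pmin(stats::runif(kw, cfg$wiggle_amp_m[1], cfg$wiggle_amp_m[2]),
                     0.12 * D),
        dur_s = stats::runif(kw, 30, 60)) else NULL
      sspec <- if (ks > 0) data.frame(
        speed_m_s = stats::runif(ks, cfg$step_speed_m_s[1], cfg$step_speed_m_s[2]),
        dur_s = pmin(stats::runif(ks, cfg$step_dur_s[1], cfg$step_dur_s[2]),
                     0.05 * D / cfg$step_speed_m_s[1])) else NULL
      prof <- simulate_dive_profile(
        T, D, wspec, sspec, swim_speed_m_s = cfg$swim_speed_m_s,
        descent_s = t_d, ascent_s = t_a, meander_m = cfg$bottom_meander_m)
    }

    off <- length(depth)
    dives <- rbind(dives, data.frame(
      dive = i, start_s = off, end_s = off + T,
      max_depth_m = prof$max_depth_m, duration_s = T, drift = is_drift))
    ph <- prof$phases; ph$dive <- i
    ph$start_s <- ph$start_s + off; ph$end_s <- ph$end_s + off
    phases <- rbind(phases, ph)
    if (nrow(prof$events)) {
      evd <- prof$events; evd$dive <- i
      evd$start_s <- evd$start_s + off; evd$end_s <- evd$end_s + off
      events <- rbind(events, evd)
    }
    dive_span <- rbind(dive_span, data.frame(dive = i, start_s = off,
                                             end_s = off + T))

    hdg <- stats::runif(1, 0, 360)
    # heading: constant in transit, random walk at bottom, continuous after
    bs <- ph$start_s[2] - off; be <- ph$end_s[2] - off
    hb <- hdg + cumsum(stats::rnorm(be - bs, 0, cfg$heading_walk_sd))
    hvec <- c(rep(hdg, bs), hb, rep(hb[length(hb)], T - be))
    depth <- c(depth, prof$depth)
    smult <- rep(1, T)
    if (is_drift) smult[seq(ph$start_s[2] - off + 1, ph$end_s[2] - off)] <- 0
    strok <- c(strok, smult)
    head_tgt <- c(head_tgt, hvec)

    sd_dur <- round(stats::runif(1, cfg$surface_duration_s[1],
                                 cfg$surface_duration_s[2]))
    surf_mid <- c(surf_mid, length(depth) + sd_dur / 2)
    add_surface(sd_dur, hvec[length(hvec)])
    hdg_prev <- hdg
  }
  if (n == 0 && length(depth) < 600) add_surface(600 - length(depth), hdg_prev)

  nsec <- length(depth)
  # true orientation at 1 Hz; pitch from the depth rate for physical
  # consistency (vertical speed = swim speed * sin(|pitch|))
  r <- c(diff(depth), 0)
  pitch <- rad2deg(-asin(pmin(pmax(r / cfg$swim_speed_m_s, -0.999), 0.999)))
  heading <- moving_average(head_tgt, 31L) # smooth below the 0.2 Hz filter band
  # gentle body roll while submerged, level at the surface
  roll <- 5 * sin(2 * pi * 0.008 * seq_len(nsec)) *
    moving_average(as.numeric(depth > 0.5), 31L)

  # upsample orientation to 16 Hz
  tt1 <- seq_len(nsec) - 1
  tt16 <- (seq_len(nsec * fs) - 1) / fs
  up <- function(x) stats::approx(tt1, x, xout = tt16, rule = 2)$y
  th <- deg2rad(up(pitch)); phn <- deg2rad(up(roll)); ps <- deg2rad(up(heading))

  # gravity in body frame (down vector), yaw drops out
  acc <- cbind(-sin(th), sin(phn) * cos(th), cos(phn) * cos(th))
  # magnetometer: NED field through yaw, pitch, roll (passive rotations)
  mN <- cfg$mag_field[1]; mE <- cfg$mag_field[2]; mD <- cfg$mag_field[3]
  v1x <- cos(ps) * mN + sin(ps) * mE
  v1y <- -sin(ps) * mN + cos(ps) * mE
  v2x <- cos(th) * v1x - sin(th) * mD
  v2z <- sin(th) * v1x + cos(th) * mD
  mag <- cbind(v2x,
               cos(phn) * v1y + sin(phn) * v2z,
               -sin(phn) * v1y + cos(phn) * v2z)

  # lateral stroking
  acc[, 2] <- acc[, 2] + cfg$stroke_amp * up(strok) *
    sin(2 * pi * cfg$stroke_freq_hz * tt16)

  # prey-encounter bursts within phases of non-drift dives
  pee <- data.frame()
  if (nrow(phases)) {
    act <- phases[!(phases$dive %in% drift_ids), ]
    for (j in seq_len(nrow(act))) {
      span_min <- (act$end_s[j] - act$start_s[j]) / 60
      lam <- cfg$pee_per_bottom_min * span_min
      if (act$phase[j] != "bottom") lam <- lam * cfg$pee_transit_frac / 2
      nb <- stats::rpois(1, lam)
      if (nb > 0) {
        durs <- stats::runif(nb, cfg$burst_dur_s[1], cfg$burst_dur_s[2])
        pl <- place_bursts(nb, durs, act$start_s[j], act$end_s[j])
        if (nrow(pl)) {
          pl$dive <- act$dive[j]; pl$phase <- act$phase[j]
          pee <- rbind(pee, pl)
        }
      }
    }
  }
  if (nrow(pee)) {
    pee <- pee[order(pee$start_s), ]
    for (j in seq_len(nrow(pee))) {
      i0 <- floor(pee$start_s[j] * fs) + 1
      len <- max(round((pee$end_s[j] - pee$start_s[j]) * fs), 8)
      idx <- i0:min(i0 + len - 1, nrow(acc))
      for (ax in 1:3) {
        acc[idx, ax] <- acc[idx, ax] + cfg$burst_amp * burst_waveform(length(idx))
      }
    }
  } else {
    pee <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      dive = integer(0), phase = character(0))
  }

  # two-axis negative-control bursts (X and Y only), kept clear of true PEEs
  pee_neg <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (cfg$n_two_axis_bursts > 0 && nrow(phases)) {
    bots <- phases[phases$phase == "bottom" & !(phases$dive %in% drift_ids), ]
    per <- ceiling(cfg$n_two_axis_bursts / nrow(bots))
    for (j in seq_len(nrow(bots))) {
      if (nrow(pee_neg) >= cfg$n_two_axis_bursts) break
      durs <- stats::runif(per, cfg$burst_dur_s[1], cfg$burst_dur_s[2])
      pl <- place_bursts(per, durs, bots$start_s[j], bots$end_s[j])
      if (nrow(pee) && nrow(pl)) { # drop controls overlapping real bursts
        keep <- vapply(seq_len(nrow(pl)), function(q) {
          !any(pl$start_s[q] < pee$end_s + 2 & pl$end_s[q] > pee$start_s - 2)
        }, logical(1))
        pl <- pl[keep, , drop = FALSE]
      }
      if (nrow(pl)) pee_neg <- rbind(pee_neg, pl)
    }
    if (nrow(pee_neg) > cfg$n_two_axis_bursts) {
      pee_neg <- pee_neg[seq_len(cfg$n_two_axis_bursts), ]
    }
    for (j in seq_len(nrow(pee_neg))) {
      i0 <- floor(pee_neg$start_s[j] * fs) + 1
      len <- max(round((pee_neg$end_s[j] - pee_neg$start_s[j]) * fs), 8)
      idx <- i0:min(i0 + len - 1, nrow(acc))
      for (ax in 1:2) {
        acc[idx, ax] <- acc[idx, ax] + cfg$burst_amp * burst_waveform(length(idx))
      }
    }
  }

  if (cfg$noise_sd > 0) {
    acc <- acc + matrix(stats::rnorm(length(acc), 0, cfg$noise_sd), ncol = 3)
    mag <- mag + matrix(stats::rnorm(length(mag), 0, 0.1), ncol = 3)
  }

  # depth channel: quantize to 0.5 m resolution, then add sensor drift
  offset_true <- cfg$pressure_drift_m_per_h * (tt1 / 3600)
  depth_obs <- round(depth / 0.5) * 0.5 + offset_true

  # GPS fixes: cumulative surface track, fix with probability gps_fix_prob
  gps <- data.frame(time_s = numeric(0), lat = numeric(0), lon = numeric(0))
  lat <- cfg$start_lat; lon <- cfg$start_lon
  prev_t <- surf_mid[1]
  for (j in seq_along(surf_mid)) {
    if (j > 1) {
      sp <- stats::runif(1, 0.2, 0.8)
      brg <- deg2rad(stats::runif(1, 0, 360))
      d <- sp * (surf_mid[j] - prev_t)
      lat <- lat + d * cos(brg) / 111320
      lon <- lon + d * sin(brg) / (111320 * cos(deg2rad(lat)))
      prev_t <- surf_mid[j]
    }
    if (stats::runif(1) < cfg$gps_fix_prob) {
      gps <- rbind(gps, data.frame(time_s = surf_mid[j], lat = lat, lon = lon))
    }
  }

  deployment <- structure(list(
    depth = depth_obs, fs_depth = 1L,
    acc = acc, mag = mag, fs_acc = fs,
    gps = gps, start_time = cfg$start_time,
    individual = cfg$individual, config = cfg), class = "ses_deployment")

  truth <- structure(list(
    dives = dives, phases = phases, events = events,
    pee = pee, pee_negative = pee_neg,
    orientation = data.frame(pitch = pitch, roll = roll,
                             heading = wrap360(heading)),
    depth_true = depth, offset_true = offset_true,
    stroke_mask = strok, drift_dives = drift_ids,
    config = cfg), class = "ses_truth")

  list(deployment = deployment, truth = truth)
}

#' Simulate a dive-level covariate table with known parameters
#'
#' Draws a regression table matching the structure of the pipeline's
#' statistical models, for parameter-recovery and selection experiments:
#' negative-binomial counts with a log bottom-duration exposure offset
#' (`family = "nb"`), a Gaussian random-intercept mixed model optionally
#' with a two-level phase factor interacting with every covariate
#' (`family = "lmm"`), or a variable-dispersion beta response
#' (`family = "beta"`, logit mean link, log precision link).
#'
#' @param n_dives rows to draw.
#' @param n_individuals number of individuals (rows split evenly, in time
#'   order within individual).
#' @param coefs named list: `intercept`; `slopes` (named vector, one per
#'   covariate); family extras: `theta` (nb dispersion), `sd_individual` and
#'   `sd_residual` (lmm), `phi_intercept` and `phi_slopes` (beta precision
#'   submodel), `individual_effects` (fixed intercept shifts, nb/beta),
#'   `phase_slopes` (lmm interaction contrasts, named like `slopes`).
#' @param family `"nb"`, `"lmm"` or `"beta"`.
#' @param seed RNG seed.
#' @param exposure_range_min bottom-duration range in minutes (nb offset).
#' @return list with `table` (data.frame) and `truth` (the drawn parameters,
#'   including per-individual effects).
#' @export
simulate_covariate_table <- function(n_dives, n_individuals, coefs,
                                     family = c("nb", "lmm", "beta"),
                                     seed = 1L,
                                     exposure_range_min = c(3, 12)) {
  family <- match.arg(family)
  set.seed(seed)
  k <- length(coefs$slopes)
  xn <- names(coefs$slopes)
  if (is.null(xn) && k > 0) xn <- paste0("x", seq_len(k))
  X <- matrix(stats::rnorm(n_dives * k), ncol = k, dimnames = list(NULL, xn))
  ind <- factor(rep(paste0("ind", sprintf("%02d", seq_len(n_individuals))),
                    length.out = n_dives))
  ind <- ind[order(ind)]
  tab <- data.frame(individual = ind)
  if (k > 0) tab <- data.frame(tab, X, check.names = FALSE)
  eta <- coefs$intercept +
    (if (k > 0) as.numeric(X %*% coefs$slopes) else 0)

  truth <- coefs
  if (family == "nb") {
    fe <- coefs$individual_effects
    if (is.null(fe)) fe <- rep(0, n_individuals)
    eta <- eta + fe[as.integer(ind)]
    expo <- stats::runif(n_dives, exposure_range_min[1], exposure_range_min[2])
    mu <- exp(eta + log(expo))
    tab$bottom_duration_min <- expo
    tab$count <- if (is.finite(coefs$theta)) {
      stats::rnbinom(n_dives, mu = mu, size = coefs$theta)
    } else stats::rpois(n_dives, mu)
    truth$individual_effects <- fe
  } else if (family == "lmm") {
    u <- stats::rnorm(n_individuals, 0, coefs$sd_individual)
    eta <- eta + u[as.integer(ind)]
    if (!is.null(coefs$phase_slopes)) {
      phase <- factor(rep(c("descent", "ascent"), length.out = n_dives),
                      levels = c("descent", "ascent"))
      eta <- eta + (phase == "ascent") *
        (coefs$phase_intercept + as.numeric(X %*% coefs$phase_slopes))
      tab$phase <- phase
    }
    tab$y <- eta + stats::rnorm(n_dives, 0, coefs$sd_residual)
    truth$individual_effects <- u
  } else {
    fe <- coefs$individual_effects
    if (is.null(fe)) fe <- rep(0, n_individuals)
    eta <- eta + fe[as.integer(ind)]
    mu <- stats::plogis(eta)
    phi <- exp(coefs$phi_intercept +
                 as.numeric(X %*% coefs$phi_slopes[xn]))
    y <- stats::rbeta(n_dives, mu * phi, (1 - mu) * phi)
    clamped <- y <= 0 | y >= 1
    eps <- .Machine$double.eps
    y[y <= 0] <- eps
    y[y >= 1] <- 1 - eps
    tab$y <- y
    truth$individual_effects <- fe
    truth$n_clamped <- sum(clamped)
    if (any(clamped)) {
      warning(sprintf("%d beta responses clamped away from {0,1}", sum(clamped)))
    }
  }
  list(table = tab, truth = truth)
}
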