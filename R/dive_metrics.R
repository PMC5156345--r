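#' Prey-encounter rate at the bottom
#'
#' Count of bottom-phase events divided by the bottom duration in minutes.
#'
#' @param count number of events in the bottom phase.
#' @param bottom_duration_min bottom duration in minutes (> 0).
#' @return rate per minute.
#' @export
pee_rate_bottom <- function(count, bottom_duration_min) {
  if (any(bottom_duration_min <= 0)) stop("bottom duration must be positive")
  count / bottom_duration_min
}

#' Bottom vertical extent
#'
#' Depth range between the 10% and 90% quantiles of the 1 Hz depth samples
#' in the bottom phase (linear interpolation between order statistics,
#' quantile type 7). A robust measure of the thickness of the water-column
#' layer exploited during the bottom phase.
#'
#' @param depths bottom-phase depth samples (>= 2).
#' @return metres (>= 0).
#' @export
bottom_vertical_extent <- function(depths) {
  if (length(depths) < 2) stop("need at least 2 bottom samples")
  q <- stats::quantile(depths, c(0.1, 0.9), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Percentage of the bottom phase covered by events
#'
#' @param bottom_start,bottom_end bottom phase interval (half-open seconds).
#' @param events event data.frame with `kind`, `start_s`, `end_s`.
#' @param kind `"wiggle"` or `"step"`.
#' @return percentage in \[0, 100\].
#' @export
pct_bottom_in_events <- function(bottom_start, bottom_end, events, kind) {
  dur <- bottom_end - bottom_start
  if (dur <= 0) stop("empty bottom phase")
  ev <- events[events$kind == kind, , drop = FALSE]
  if (!nrow(ev)) return(0)
  cov <- sum(overlap_seconds(ev$start_s, ev$end_s, bottom_start, bottom_end))
  100 * cov / dur
}

#' Dive efficiency
#'
#' Bottom-phase duration divided by total dive duration; strictly inside
#' (0, 1) whenever both transit phases are non-empty. Degenerate ratios at
#' exactly 0 or 1 are flagged via attribute `"flagged"` (such records are
#' excluded from the beta regression).
#'
#' @param bottom_s bottom duration (s).
#' @param dive_s dive duration (s).
#' @return proportion with attribute `"flagged"`.
#' @export
dive_efficiency <- function(bottom_s, dive_s) {
  if (any(dive_s <= 0)) stop("dive duration must be positive")
  eff <- bottom_s / dive_s
  flagged <- which(eff <= 0 | eff >= 1)
  attr(eff, "flagged") <- flagged
  eff
}

#' Horizontal speed between bracketing surface fixes
#'
#' Haversine great-circle distance (sphere radius 6 371 008.8 m) between
#' the GPS fixes before and after a dive, divided by the elapsed time
#' between the fixes.
#'
#' @param lat1,lon1,t1 fix preceding the dive (degrees, seconds).
#' @param lat2,lon2,t2 fix following the dive.
#' @return speed in m/s.
#' @export
surface_speed <- function(lat1, lon1, t1, lat2, lon2, t2) {
  if (any(t2 <= t1)) stop("fixes must be time-ordered")
  d <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                r = 6371008.8)
  d / (t2 - t1)
}

#' Solar altitude
#'
#' Compact solar-position algorithm (low-precision ephemeris: mean solar
#' longitude and anomaly, ecliptic to equatorial conversion, Greenwich
#' sidereal time), accurate to a small fraction of a degree - ample for
#' day/night classification.
#'
#' @param time POSIXct (UTC).
#' @param lat,lon position in decimal degrees.
#' @return solar altitude above the horizon, degrees.
#' @export
solar_altitude <- function(time, lat, lon) {
  n <- as.numeric(difftime(time, as.POSIXct("2000-01-01 12:00:00", tz = "UTC"),
                           units = "days"))
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- deg2rad((357.528 + 0.9856003 * n) %% 360)
  lambda <- deg2rad(L + 1.915 * sin(g) + 0.020 * sin(2 * g))
  eps <- deg2rad(23.439 - 4e-7 * n)
  decl <- asin(sin(eps) * sin(lambda))
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda))
  gmst_h <- (18.697374558 + 24.06570982441908 * n) %% 24
  ha <- deg2rad(wrap360(gmst_h * 15 + lon - rad2deg(ra)))
  phi <- deg2rad(lat)
  rad2deg(asin(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)))
}

#' Classify a dive as day or night
#'
#' Day if the solar altitude at the dive start, at the position linearly
#' interpolated between the bracketing GPS fixes, is at or above
#' `threshold_deg` (0 degrees; the boundary itself counts as day). Returns
#' `NA` when no fix lies within 24 h of the dive start.
#'
#' @param time_s dive start (seconds into the record).
#' @param gps data.frame of fixes with `time_s`, `lat`, `lon`.
#' @param start_time POSIXct start of the record (UTC).
#' @param threshold_deg altitude threshold, default 0.
#' @return `"day"`, `"night"` or `NA`.
#' @export
classify_day_night <- function(time_s, gps, start_time, threshold_deg = 0) {
  if (!nrow(gps) || min(abs(gps$time_s - time_s)) > 86400) return(NA_character_)
  lat <- stats::approx(gps$time_s, gps$lat, xout = time_s, rule = 2)$y
  lon <- stats::approx(gps$time_s, gps$lon, xout = time_s, rule = 2)$y
  alt <- solar_altitude(start_time + time_s, lat, lon)
  if (alt >= threshold_deg) "day" else "night"
}

#' Assemble the per-dive covariate table
#'
#' Runs the whole per-dive metric stage over the outputs of segmentation,
#' event detection and orientation, producing one row per non-excluded dive
#' (duration bounds respected, drift dives removed). Missing values occur
#' only in `surface_speed_m_s` (dives without bracketing GPS fixes) and
#' `daynight` (no usable fix within a day). Rows whose bottom phase is
#' degenerate are dropped with a message, never silently.
#'
#' @param deployment a `ses_deployment` (for GPS, start time, individual).
#' @param seg segmentation result from [segment_deployment()].
#' @param pee_events detected events from [detect_pee()].
#' @param orient 1 Hz orientation from [orientation_series()].
#' @param effort 1 Hz swimming effort.
#' @return data.frame, one row per analysable dive; attribute
#'   `"dropped"` lists dropped dive ids.
#' @export
build_dive_table <- function(deployment, seg, pee_events, orient, effort) {
  dives <- seg$dives
  keep <- dives$excluded == "none" & !dives$drift
  pee <- assign_events_to_phases(pee_events, seg$phases)
  rows <- list()
  dropped <- integer(0)
  for (i in which(keep)) {
    d <- dives[i, ]
    ph <- seg$phases[seg$phases$dive == d$dive, ]
    bot <- ph[ph$phase == "bottom", ]
    des <- ph[ph$phase == "descent", ]
    asc <- ph[ph$phase == "ascent", ]
    bdur <- bot$end_s - bot$start_s
    if (bdur <= 1 || des$end_s <= des$start_s || asc$end_s <= asc$start_s) {
      dropped <- c(dropped, d$dive)
      next
    }
    ev <- seg$events[seg$events$dive == d$dive, , drop = FALSE]
    bsam <- interval_samples(bot$start_s, bot$end_s)
    dsam <- interval_samples(des$start_s, des$end_s)
    asam <- interval_samples(asc$start_s, asc$end_s)
    npee <- sum(pee$dive == d$dive & pee$phase == "bottom", na.rm = TRUE)
    bmin <- bdur / 60

    gb <- deployment$gps[deployment$gps$time_s <= d$start_s, , drop = FALSE]
    ga <- deployment$gps[deployment$gps$time_s >= d$end_s, , drop = FALSE]
    sspeed <- NA_real_
    if (nrow(gb) && nrow(ga)) {
      # only fixes at the immediately adjacent surfacings give a dive-scale
      # speed; allow one surface interval of slack on either side
      f1 <- gb[nrow(gb), ]; f2 <- ga[1, ]
      if (d$start_s - f1$time_s < 600 && f2$time_s - d$end_s < 600) {
        sspeed <- surface_speed(f1$lat, f1$lon, f1$time_s,
                                f2$lat, f2$lon, f2$time_s)
      }
    }

    eff <- dive_efficiency(bdur, d$duration_s)
    rows[[length(rows) + 1]] <- data.frame(
      individual = deployment$individual,
      dive_id = d$dive,
      start_s = d$start_s,
      daynight = classify_day_night(d$start_s, deployment$gps,
                                    deployment$start_time),
      max_depth_m = d$max_depth_m,
      dive_duration_s = d$duration_s,
      bottom_duration_min = bmin,
      bottom_pee_count = npee,
      pee_rate_bottom = pee_rate_bottom(npee, bmin),
      bottom_median_depth_m = stats::median(seg$depth_corrected[bsam]),
      bottom_vertical_extent_m =
        bottom_vertical_extent(seg$depth_corrected[bsam]),
      pct_bottom_wiggle = pct_bottom_in_events(bot$start_s, bot$end_s, ev,
                                               "wiggle"),
      pct_bottom_step = pct_bottom_in_events(bot$start_s, bot$end_s, ev,
                                             "step"),
      mean_pitch_descent_deg = circular_mean(orient$pitch[dsam]),
      mean_pitch_ascent_deg = circular_mean(orient$pitch[asam]),
      mean_effort_descent = mean(effort[dsam]),
      mean_effort_ascent = mean(effort[asam]),
      var_pitch_bottom = circular_variance(orient$pitch[bsam]),
      var_heading_bottom = circular_variance(orient$heading[bsam]),
      dive_efficiency = as.numeric(eff),
      surface_speed_m_s = sspeed,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (length(dropped)) {
    message("dropped dives with degenerate phases: ",
            paste(dropped, collapse = ", "))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Assemble the per-transit-phase table
#'
#' One row per descent and ascent phase of each analysable dive, for the
#' phase-duration model: phase type, duration, maximum depth reached in the
#' phase and mean swimming effort.
#'
#' @inheritParams build_dive_table
#' @return data.frame with columns `individual`, `dive_id`, `phase`,
#'   `duration_s`, `phase_max_depth_m`, `mean_effort`.
#' @export
build_phase_table <- function(deployment, seg, effort) {
  dives <- seg$dives
  keep <- dives$excluded == "none" & !dives$drift
  rows <- list()
  for (i in which(keep)) {
    d <- dives[i, ]
    ph <- seg$phases[seg$phases$dive == d$dive &
                       seg$phases$phase %in% c("descent", "ascent"), ]
    for (j in seq_len(nrow(ph))) {
      sam <- interval_samples(ph$start_s[j], ph$end_s[j])
      if (!length(sam)) next
      rows[[length(rows) + 1]] <- data.frame(
        individual = deployment$individual,
        dive_id = d$dive,
        phase = ph$phase[j],
        duration_s = ph$end_s[j] - ph$start_s[j],
        phase_max_depth_m = max(seg$depth_corrected[sam]),
        mean_effort = mean(effort[sam]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else data.frame()
}
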