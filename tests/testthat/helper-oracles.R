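# Independent brute-force oracles, deliberately written as naive loops over
# the stated definitions so they share no code with the implementation.

# Two-pass sample SD.
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Moving SD with centred window and >= 3-sample edge windows.
oracle_moving_sd <- function(x, window = 5) {
  n <- length(x)
  half <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    if (hi - lo + 1 < 3) {
      if (lo == 1) hi <- min(3, n) else lo <- max(1, n - 2)
    }
    out[i] <- oracle_sd(x[lo:hi])
  }
  out
}

# Exhaustive 1-D two-cluster split minimizing total within-cluster SS.
oracle_two_means <- function(values) {
  s <- sort(values)
  n <- length(s)
  best <- Inf; bestk <- 1
  for (k in 1:(n - 1)) {
    lo <- s[1:k]; hi <- s[(k + 1):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best) { best <- wss; bestk <- k }
  }
  thr <- (s[bestk] + s[bestk + 1]) / 2
  list(threshold = thr, labels = values > thr, wss = best)
}

# Direct two-pass circular statistics.
oracle_circular <- function(deg) {
  a <- deg * pi / 180
  C <- mean(cos(a)); S <- mean(sin(a))
  list(mean = atan2(S, C) * 180 / pi, var = 1 - sqrt(C^2 + S^2))
}

# Full 3-D rotation composition for heading verification: body vector of a
# NED vector under yaw (psi), pitch (theta), roll (phi), passive ZYX.
oracle_body_vector <- function(v, psi, theta, phi) {
  d <- pi / 180
  Rz <- matrix(c(cos(psi * d), sin(psi * d), 0,
                 -sin(psi * d), cos(psi * d), 0,
                 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(theta * d), 0, -sin(theta * d),
                 0, 1, 0,
                 sin(theta * d), 0, cos(theta * d)), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(phi * d), sin(phi * d),
                 0, -sin(phi * d), cos(phi * d)), 3, byrow = TRUE)
  as.numeric(Rx %*% Ry %*% Rz %*% v)
}

# Dive delimitation by per-sample state tracking.
oracle_detect_dives <- function(depth, thr = 15) {
  out <- data.frame(start_s = integer(0), end_s = integer(0))
  inside <- FALSE; s <- NA
  for (i in seq_along(depth)) {
    if (!inside && depth[i] > thr) { inside <- TRUE; s <- i - 1 }
    if (inside && depth[i] <= thr) {
      out <- rbind(out, data.frame(start_s = s, end_s = i - 1))
      inside <- FALSE
    }
  }
  if (inside) out <- rbind(out, data.frame(start_s = s, end_s = length(depth)))
  out
}

# Smoothed central-difference vertical speed, naive loops.
oracle_vertical_speed <- function(depth, w = 3) {
  n <- length(depth)
  sm <- numeric(n)
  half <- w %/% 2
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sm[i] <- mean(depth[lo:hi])
  }
  v <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1) v[i] <- sm[2] - sm[1]
    else if (i == n) v[i] <- sm[n] - sm[n - 1]
    else v[i] <- (sm[i + 1] - sm[i - 1]) / 2
  }
  v
}

# Wiggles and steps from the stated rules, naive scan.
oracle_wiggles_steps <- function(depth, vmax = 0.35, min_step = 5,
                                 min_amp = 0) {
  v <- oracle_vertical_speed(depth)
  v[abs(v) < 1e-9] <- 0 # same numerical deadband as the implementation
  n <- length(v)
  wig <- data.frame(kind = character(0), start_s = integer(0),
                    end_s = integer(0))
  mask <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (v[i] < 0) {
      j <- i
      while (j <= n && v[j] < 0) j <- j + 1
      # ascending run is samples i..j-1; needs descent before it and must
      # stop before the final sample (else it is the terminal ascent)
      desc_before <- any(v[seq_len(i - 1)] > 0)
      interior <- (j - 1) < n
      if (desc_before && interior) {
        seg <- max(i - 1, 1):(j - 1) # boundary (local max) sample included
        if (max(depth[seg]) - min(depth[seg]) >= min_amp) {
          wig <- rbind(wig, data.frame(kind = "wiggle", start_s = i - 1,
                                       end_s = j - 1))
          mask[seg] <- TRUE
        }
      }
      i <- j
    } else i <- i + 1
  }
  stp <- data.frame(kind = character(0), start_s = integer(0),
                    end_s = integer(0))
  i <- 1
  while (i <= n) {
    if (v[i] > 0 && v[i] < vmax && !mask[i]) {
      j <- i
      while (j <= n && v[j] > 0 && v[j] < vmax && !mask[j]) j <- j + 1
      if (j - i >= min_step) {
        stp <- rbind(stp, data.frame(kind = "step", start_s = i - 1,
                                     end_s = j - 1))
      }
      i <- j
    } else i <- i + 1
  }
  out <- rbind(wig, stp)
  out[order(out$start_s), , drop = FALSE]
}

# Three-phase partition from qualifying events (naive).
oracle_delimit <- function(depth, events, ledge = 0.75) {
  n <- length(depth)
  maxd <- max(depth)
  qs <- qe <- NULL
  for (i in seq_len(nrow(events))) {
    seg <- (events$start_s[i] + 1):events$end_s[i]
    seg <- c(events$start_s[i], seg) # boundary sample included for wiggles
    seg <- seg[seg >= 1 & seg <= n]
    if (max(depth[seg]) > ledge * maxd) {
      if (is.null(qs) || events$start_s[i] < qs) qs <- events$start_s[i]
      if (is.null(qe) || events$end_s[i] > qe) qe <- events$end_s[i]
    }
  }
  fallback <- is.null(qs)
  if (fallback) {
    deep <- which(depth >= ledge * maxd)
    qs <- min(deep) - 1; qe <- max(deep)
  }
  qs <- max(qs, 1); qe <- min(qe, n - 1)
  list(descent = c(0, qs), bottom = c(qs, qe), ascent = c(qe, n),
       fallback = fallback)
}

# Haversine on a sphere, closed form.
oracle_haversine <- function(lat1, lon1, lat2, lon2, R = 6371008.8) {
  d <- pi / 180
  a <- sin((lat2 - lat1) * d / 2)^2 +
    cos(lat1 * d) * cos(lat2 * d) * sin((lon2 - lon1) * d / 2)^2
  2 * R * asin(sqrt(a))
}

# A random dive-shaped record for oracle-equivalence tests: surface, one
# dive built by simulate_dive_profile with random events, surface; with
# 0.5 m quantization as in the observed channel.
random_dive_record <- function(seed) {
  set.seed(seed)
  T <- round(runif(1, 620, 1500))
  D <- runif(1, 150, 0.9 * min(0.28 * T, 0.28 * T) * 2 * 0.92)
  kw <- sample(0:3, 1); ks <- sample(0:2, 1)
  ws <- if (kw) data.frame(amp_m = pmin(runif(kw, 8, 30), 0.12 * D),
                           dur_s = runif(kw, 30, 60)) else NULL
  ss <- if (ks) data.frame(speed_m_s = runif(ks, 0.1, 0.3),
                           dur_s = runif(ks, 20, 50)) else NULL
  prof <- simulate_dive_profile(T, D, ws, ss,
                                meander_m = runif(1, 0, 0.4))
  depth <- c(rep(0, 40), round(prof$depth / 0.5) * 0.5, rep(0, 40))
  list(depth = depth, dive_offset = 40, profile = prof)
}
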