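# A clean multi-dive depth record with known surface truth.
make_depth <- function(n_dives = 4, seed = 31) {
  set.seed(seed)
  depth <- rep(0, 200)
  for (i in seq_len(n_dives)) {
    p <- simulate_dive_profile(round(runif(1, 700, 1200)),
                               runif(1, 150, 350))
    depth <- c(depth, round(p$depth / 0.5) * 0.5, rep(0, 150))
  }
  depth
}

test_that("zero offset correction recovers constant and linear drifts", {
  depth <- make_depth()
  n <- length(depth)

  z <- zero_offset_correct(depth)
  expect_lt(max(abs(z$depth - depth)), 0.51)

  z2 <- zero_offset_correct(depth + 2)
  expect_equal(mean(z2$offset), 2, tolerance = 0.3)
  expect_lt(max(abs(z2$depth[depth == 0])), 0.5)

  # 1 m/h over 12 h
  long <- rep(depth, length.out = 12 * 3600)
  drift <- (seq_along(long) - 1) / 3600
  z3 <- zero_offset_correct(long + drift)
  expect_lt(max(abs(z3$depth[long == 0])), 0.75)
})

test_that("dive delimitation applies the 15 m rule and duration flags", {
  expect_equal(nrow(detect_dives(rep(10, 5000))), 0)

  # trapezoid with known crossing samples: 0-based second i has depth[i+1]
  depth <- c(rep(0, 100), seq(1, 100, by = 1), rep(100, 800),
             seq(99, 0, by = -1), rep(0, 100))
  d <- detect_dives(depth)
  expect_equal(nrow(d), 1)
  # first sample > 15 m is depth 16 at index 116 (second 115); the last is
  # depth 16 on the way up, 83 samples into the descent limb
  expect_equal(d$start_s, 115)
  expect_equal(d$end_s, 1000 + (99 - 16) + 1)
  expect_equal(d$excluded, "none")

  short <- c(rep(0, 50), rep(100, 400), rep(0, 50))
  expect_equal(detect_dives(short)$excluded, "too_short")
  long <- c(rep(0, 50), rep(100, 2000), rep(0, 50))
  expect_equal(detect_dives(long)$excluded, "too_long")
})

test_that("vertical speed is the signed smoothed central difference", {
  down <- seq(0, 100, by = 1)
  v <- vertical_speed(down)
  expect_equal(v[5:95], rep(1, 91), tolerance = 1e-12)
  up <- seq(100, 20, by = -0.8)
  v <- vertical_speed(up)
  expect_equal(v[5:90], rep(-0.8, 86), tolerance = 1e-12)

  set.seed(32)
  prof <- simulate_dive_profile(800, 300,
                                wiggle_spec = data.frame(amp_m = 15,
                                                         dur_s = 40))
  expect_equal(vertical_speed(prof$depth),
               oracle_vertical_speed(prof$depth), tolerance = 1e-10)
})

test_that("wiggles and steps are found where they were injected", {
  p <- simulate_dive_profile(900, 400)
  expect_equal(nrow(find_wiggles_steps(p$depth)), 0)

  set.seed(33)
  p <- simulate_dive_profile(900, 400,
                             wiggle_spec = data.frame(amp_m = 20, dur_s = 40))
  ev <- find_wiggles_steps(p$depth)
  expect_equal(sum(ev$kind == "wiggle"), 1)
  tw <- p$events[p$events$kind == "wiggle", ]
  got <- ev[ev$kind == "wiggle", ]
  expect_lte(abs(got$start_s - tw$start_s), 2)
  expect_lte(abs(got$end_s - tw$end_s), 2)

  set.seed(34)
  p <- simulate_dive_profile(900, 400,
                             step_spec = data.frame(speed_m_s = 0.2,
                                                    dur_s = 30))
  ev <- find_wiggles_steps(p$depth)
  st <- ev[ev$kind == "step", ]
  ts <- p$events[p$events$kind == "step", ]
  expect_equal(nrow(st), 1)
  cover <- min(st$end_s, ts$end_s) - max(st$start_s, ts$start_s)
  expect_gte(cover / (ts$end_s - ts$start_s), 0.9)

  # every reported step obeys the strict (0, 0.35) bound; every wiggle
  # contains a sign change of vertical speed
  set.seed(35)
  for (r in 1:10) {
    rec <- random_dive_record(3500 + r)
    seg <- rec$depth[(rec$dive_offset + 1):(length(rec$depth) - 40)]
    ev <- find_wiggles_steps(seg)
    v <- vertical_speed(seg)
    for (i in which(ev$kind == "step")) {
      vv <- v[(ev$start_s[i] + 1):ev$end_s[i]]
      expect_true(all(vv > 0 & vv < 0.35))
    }
    for (i in which(ev$kind == "wiggle")) {
      vv <- v[(ev$start_s[i] + 1):ev$end_s[i]]
      expect_true(any(vv < 0))
    }
  }
})

test_that("bottom delimitation follows the 75% ledge rule", {
  set.seed(36)
  p <- simulate_dive_profile(900, 400,
                             wiggle_spec = data.frame(amp_m = 20, dur_s = 40))
  ev <- find_wiggles_steps(p$depth)
  ph <- delimit_bottom(p$depth, ev)
  expect_false(attr(ph, "fallback"))
  w <- ev[ev$kind == "wiggle", ]
  expect_equal(ph$start_s[ph$phase == "bottom"], min(w$start_s))
  expect_equal(ph$end_s[ph$phase == "bottom"], max(w$end_s))

  # only a shallow event: fallback to the ledge isobath crossing
  depth <- c(seq(0, 200, by = 2), # descent
             200 + 10 * sin(pi * (1:20) / 20) - 10 * (1:20) / 20, # 50% wiggle
             seq(190, 395, by = 2.5), rep(397, 60), # deep but event-free
             seq(395, 0, by = -2))
  ev <- find_wiggles_steps(depth)
  ev <- ev[ev$max_depth_m < 0.75 * max(depth), , drop = FALSE]
  ph <- delimit_bottom(depth, ev)
  expect_true(attr(ph, "fallback"))
  bot <- ph[ph$phase == "bottom", ]
  expect_gt(min(depth[(bot$start_s + 1):bot$end_s]), 0.7 * max(depth))

  # partition is exact on any input
  expect_equal(ph$end_s[1], ph$start_s[2])
  expect_equal(ph$end_s[2], ph$start_s[3])
  expect_equal(ph$start_s[1], 0)
  expect_equal(ph$end_s[3], length(depth))
})

test_that("segmentation equals the brute-force oracle on random dives", {
  for (r in 1:30) {
    rec <- random_dive_record(7000 + r)
    z <- zero_offset_correct(rec$depth)
    got_d <- detect_dives(z$depth)
    want_d <- oracle_detect_dives(z$depth)
    expect_equal(got_d$start_s, want_d$start_s)
    expect_equal(got_d$end_s, want_d$end_s)
    for (i in seq_len(nrow(got_d))) {
      seg <- z$depth[(got_d$start_s[i] + 1):got_d$end_s[i]]
      got_e <- find_wiggles_steps(seg)
      want_e <- oracle_wiggles_steps(seg)
      expect_equal(got_e$kind, want_e$kind)
      expect_equal(got_e$start_s, want_e$start_s)
      expect_equal(got_e$end_s, want_e$end_s)
      got_p <- delimit_bottom(seg, got_e)
      want_p <- oracle_delimit(seg, want_e)
      expect_equal(got_p$start_s, c(0, want_p$bottom[1], want_p$ascent[1]))
      expect_equal(got_p$end_s, c(want_p$descent[2], want_p$bottom[2],
                                  length(seg)))
      expect_equal(attr(got_p, "fallback"), want_p$fallback)
    }
  }
})

test_that("correction plus detection is idempotent on drift-free data", {
  depth <- make_depth(seed = 38)
  z <- zero_offset_correct(depth)
  d1 <- detect_dives(z$depth)
  z2 <- zero_offset_correct(z$depth)
  d2 <- detect_dives(z2$depth)
  expect_equal(d1$start_s, d2$start_s)
  expect_equal(d1$end_s, d2$end_s)
})

test_that("drift dives are flagged by the passive-segment rule", {
  # constructed drift dive: no effort, constant 0.3 m/s sink for 400 s
  depth <- c(seq(0, 200, by = 2), 200 + 0.3 * (1:400),
             seq(320, 0, by = -2))
  effort <- rep(0.01, length(depth))
  expect_true(flag_drift_dives(depth, effort, effort_threshold = 0.05))

  # active dive: continuous stroking
  effort_hi <- rep(0.2, length(depth))
  expect_false(flag_drift_dives(depth, effort_hi, effort_threshold = 0.05))

  # low-effort segment shorter than 200 s does not qualify
  effort_short <- rep(0.2, length(depth))
  effort_short[150 + 1:100] <- 0.01
  expect_false(flag_drift_dives(depth, effort_short,
                                effort_threshold = 0.05))
})
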