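test_that("per-dive scalar metrics follow their definitions", {
  expect_equal(pee_rate_bottom(0, 6), 0)
  expect_equal(pee_rate_bottom(12, 6), 2)
  expect_error(pee_rate_bottom(3, 0), "positive")
  # unit coherence: seconds-based computation converts consistently
  expect_equal(pee_rate_bottom(7, 432 / 60), 7 / 432 * 60, tolerance = 1e-12)

  expect_equal(bottom_vertical_extent(rep(400, 50)), 0)
  expect_equal(bottom_vertical_extent(seq(100, 200, length.out = 101)), 80,
               tolerance = 1e-9)
  set.seed(41)
  x <- runif(200, 300, 500)
  expect_equal(bottom_vertical_extent(x),
               bottom_vertical_extent(sample(x)), tolerance = 1e-12)

  ev <- data.frame(kind = "wiggle", start_s = 100, end_s = 160)
  expect_equal(pct_bottom_in_events(50, 350, ev, "wiggle"), 20)
  expect_equal(pct_bottom_in_events(50, 350, ev, "step"), 0)
  # coverage arithmetic: non-overlapping wiggles + steps never exceed 100%
  set.seed(42)
  for (r in 1:20) {
    k <- sample(2:6, 1)
    bounds <- sort(sample(0:300, 2 * k))
    evr <- data.frame(kind = sample(c("wiggle", "step"), k, replace = TRUE),
                      start_s = bounds[seq(1, 2 * k, 2)],
                      end_s = bounds[seq(2, 2 * k, 2)])
    tot <- pct_bottom_in_events(0, 300, evr, "wiggle") +
      pct_bottom_in_events(0, 300, evr, "step")
    expect_lte(tot, 100 + 1e-9)
  }

  eff <- dive_efficiency(477, 1103)
  expect_equal(as.numeric(eff), 0.4325, tolerance = 1e-4)
  expect_length(attr(dive_efficiency(0, 100), "flagged"), 1)
  set.seed(43)
  for (r in 1:20) {
    b <- runif(1, 1, 99)
    expect_true(as.numeric(dive_efficiency(b, 100)) > 0 &&
                  as.numeric(dive_efficiency(b, 100)) < 1)
  }
})

test_that("surface speed uses the haversine metric correctly", {
  expect_equal(surface_speed(-49, 70, 0, -49, 70, 600), 0)
  # 0.01 degrees of latitude in 600 s
  sp <- surface_speed(-49, 70, 0, -48.99, 70, 600)
  expect_equal(sp, 1112.0 / 600, tolerance = 0.005)
  expect_error(surface_speed(-49, 70, 600, -48.99, 70, 100), "ordered")

  # against the closed form and an independent ellipsoidal oracle
  set.seed(44)
  for (r in 1:20) {
    la1 <- runif(1, -60, -40); lo1 <- runif(1, 60, 80)
    la2 <- la1 + runif(1, -0.3, 0.3); lo2 <- lo1 + runif(1, -0.3, 0.3)
    d_hav <- surface_speed(la1, lo1, 0, la2, lo2, 1)
    expect_equal(d_hav, oracle_haversine(la1, lo1, la2, lo2),
                 tolerance = 1e-9)
    d_geo <- geosphere::distGeo(c(lo1, la1), c(lo2, la2))
    expect_equal(d_hav, d_geo, tolerance = 0.005)
  }
})

test_that("day/night classification matches solar geometry", {
  gps <- data.frame(time_s = c(0, 200000), lat = c(0, 0), lon = c(0, 0))
  equinox_noon <- as.POSIXct("2026-03-20 12:07:00", tz = "UTC")
  expect_equal(classify_day_night(3600, gps, equinox_noon - 3600), "day")
  equinox_midnight <- as.POSIXct("2026-03-20 00:07:00", tz = "UTC")
  expect_equal(classify_day_night(3600, gps, equinox_midnight - 3600),
               "night")
  expect_gt(solar_altitude(equinox_noon, 0, 0), 85)
  expect_lt(solar_altitude(equinox_midnight, 0, 0), -85)
  # boundary convention: altitude exactly at threshold counts as day
  expect_equal(classify_day_night(0, gps, equinox_noon,
                                  threshold_deg = -90), "day")
  # no fix within 24 h: missing label
  far <- data.frame(time_s = 9e5, lat = 0, lon = 0)
  expect_true(is.na(classify_day_night(0, far, equinox_noon)))
})

test_that("the dive table is consistent with its inputs and truth", {
  sim <- default_sim()
  an <- cached("default_analysis", suppressWarnings(suppressMessages(
    analyze_deployment(sim$deployment))))
  dt <- an$dive_table

  # drift and out-of-bounds dives are absent
  n_expected <- nrow(sim$truth$dives) - length(sim$truth$drift_dives)
  expect_equal(nrow(dt) + length(attr(dt, "dropped")), n_expected)

  # conservation: total bottom counts equal events assigned to bottoms of
  # analysed dives
  pee <- assign_events_to_phases(an$events, an$segmentation$phases)
  kept <- dt$dive_id
  expect_equal(sum(dt$bottom_pee_count),
               sum(pee$phase == "bottom" & pee$dive %in% kept, na.rm = TRUE))

  # ranges and identities
  expect_true(all(dt$var_pitch_bottom >= 0 & dt$var_pitch_bottom <= 1))
  expect_true(all(dt$var_heading_bottom >= 0 & dt$var_heading_bottom <= 1))
  expect_true(all(dt$dive_efficiency > 0 & dt$dive_efficiency < 1))
  expect_true(all(dt$pct_bottom_wiggle >= 0 & dt$pct_bottom_wiggle <= 100))
  expect_equal(dt$pee_rate_bottom,
               dt$bottom_pee_count / dt$bottom_duration_min,
               tolerance = 1e-12)
  expect_true(all(!is.na(dt$daynight)))

  # metrics equal an oracle recomputation on a sample of dives
  seg <- an$segmentation
  set.seed(45)
  for (i in sample(seq_len(nrow(dt)), 10)) {
    row <- dt[i, ]
    ph <- seg$phases[seg$phases$dive == row$dive_id, ]
    bot <- ph[ph$phase == "bottom", ]
    bsam <- (bot$start_s + 1):bot$end_s
    expect_equal(row$bottom_median_depth_m,
                 median(seg$depth_corrected[bsam]), tolerance = 1e-9)
    q <- quantile(seg$depth_corrected[bsam], c(0.1, 0.9), names = FALSE)
    expect_equal(row$bottom_vertical_extent_m, q[2] - q[1],
                 tolerance = 1e-9)
    expect_equal(row$bottom_duration_min, (bot$end_s - bot$start_s) / 60,
                 tolerance = 1e-9)
  }
})

test_that("an empty deployment yields an empty table with full structure", {
  sim <- simulate_deployment(sim_config(seed = 51, n_dives = 0,
                                        n_drift_dives = 0))
  an <- suppressWarnings(suppressMessages(analyze_deployment(sim$deployment)))
  expect_equal(nrow(an$dive_table), 0)
  expect_equal(nrow(an$phase_table), 0)
})

test_that("deployments round-trip through the delimited-text format", {
  sim <- simulate_deployment(sim_config(seed = 52, n_dives = 2,
                                        n_drift_dives = 0))
  dir <- tempfile("dep")
  write_deployment(sim$deployment, dir, truth = sim$truth)
  expect_true(all(file.exists(file.path(dir, c("depth.csv", "acc.csv",
                                               "mag.csv", "gps.csv",
                                               "truth.csv",
                                               "manifest.csv")))))
  back <- read_deployment(dir)
  expect_equal(back$depth, sim$deployment$depth, tolerance = 1e-6)
  expect_equal(back$fs_acc, 16)
  expect_equal(dim(back$acc), dim(sim$deployment$acc))
  unlink(dir, recursive = TRUE)
})
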