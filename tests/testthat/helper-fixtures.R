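# Shared fixtures, built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# The default study deployment (seed 42) with negative-control bursts.
default_sim <- function() {
  cached("default_sim", suppressWarnings(
    simulate_deployment(sim_config(seed = 42, n_two_axis_bursts = 50))))
}

# A small noise-free deployment for orientation recovery.
noisefree_sim <- function() {
  cached("noisefree_sim", suppressWarnings(
    simulate_deployment(sim_config(seed = 7, n_dives = 8, noise_sd = 0,
                                   pee_per_bottom_min = 0,
                                   n_drift_dives = 0))))
}

# Dive + phase tables from three small deployments (three individuals).
multi_tables <- function() {
  cached("multi_tables", {
    dts <- list(); pts <- list()
    for (i in 1:3) {
      sim <- simulate_deployment(
        sim_config(seed = 100 + i, n_dives = 40,
                   individual = sprintf("ind%02d", i)))
      an <- suppressWarnings(suppressMessages(
        analyze_deployment(sim$deployment)))
      dts[[i]] <- an$dive_table
      pts[[i]] <- an$phase_table
    }
    list(dive = do.call(rbind, dts), phase = do.call(rbind, pts))
  })
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Circular difference a - b wrapped to (-180, 180].
ang_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  d
}

# Interval overlap with slack for the 1 Hz state timeline.
overlaps_any <- function(s, e, starts, ends, slack = 1) {
  any(s < ends + slack & e > starts - slack)
}
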