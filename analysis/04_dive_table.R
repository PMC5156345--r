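#!/usr/bin/env Rscript
# Step 4: per-dive covariate table. Orientation (pitch/roll/heading at
# 1 Hz), prey-encounter rate at the bottom, bottom median depth and
# vertical extent, wiggle/step coverage, circular means/variances, dive
# efficiency, surface horizontal speed from bracketing GPS fixes and
# day/night from solar altitude.

library(sesforage)

dts <- list(); pts <- list()
for (i in 1:3) {
  sim <- readRDS(sprintf("results/cache/dep%02d.rds", i))
  sg <- readRDS(sprintf("results/cache/seg%02d.rds", i))
  ev <- readRDS(sprintf("results/cache/events%02d.rds", i))
  orient <- orientation_series(sim$deployment$acc, sim$deployment$mag)
  dts[[i]] <- build_dive_table(sim$deployment, sg$seg, ev, orient,
                               sg$effort)
  pts[[i]] <- build_phase_table(sim$deployment, sg$seg, sg$effort)
}
dt <- do.call(rbind, dts); pt <- do.call(rbind, pts)
write.csv(dt, "results/dive_table.csv", row.names = FALSE)
write.csv(pt, "results/phase_table.csv", row.names = FALSE)
cat(sprintf(
  "%d analysable dives (%d with surface speed, %d day / %d night)\n",
  nrow(dt), sum(!is.na(dt$surface_speed_m_s)),
  sum(dt$daynight == "day", na.rm = TRUE),
  sum(dt$daynight == "night", na.rm = TRUE)))
cat(sprintf("mean PEE rate at bottom: %.2f per min; mean dive efficiency: %.2f\n",
            mean(dt$pee_rate_bottom), mean(dt$dive_efficiency)))
cat("wrote results/dive_table.csv, results/phase_table.csv\n")
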