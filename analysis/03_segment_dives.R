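#!/usr/bin/env Rscript
# Step 3: depth-channel processing. Zero offset correction of the pressure
# drift, dive delimitation (15 m threshold, 500-1950 s duration flags),
# wiggle/step detection, 75%-ledge bottom delimitation and drift-dive
# flagging against the swimming-effort series.

library(sesforage)

dives <- list(); phases <- list(); events <- list()
for (i in 1:3) {
  sim <- readRDS(sprintf("results/cache/dep%02d.rds", i))
  eff <- swimming_effort(sim$deployment$acc[, 2])
  seg <- segment_deployment(sim$deployment$depth, eff)
  saveRDS(list(seg = seg, effort = eff),
          sprintf("results/cache/seg%02d.rds", i))
  id <- sim$deployment$individual
  cat(sprintf(
    "%s: %d dives (%d drift, %d excluded, %d fallback delimitations), %d bottom events\n",
    id, nrow(seg$dives), sum(seg$dives$drift),
    sum(seg$dives$excluded != "none"), sum(seg$dives$fallback),
    nrow(seg$events)))
  seg$dives$individual <- id
  if (nrow(seg$phases)) seg$phases$individual <- id
  if (nrow(seg$events)) seg$events$individual <- id
  dives[[i]] <- seg$dives; phases[[i]] <- seg$phases
  events[[i]] <- seg$events
}
write.csv(do.call(rbind, dives), "results/dives.csv", row.names = FALSE)
write.csv(do.call(rbind, phases), "results/phases.csv", row.names = FALSE)
write.csv(do.call(rbind, events), "results/bottom_events.csv",
          row.names = FALSE)
cat("wrote results/dives.csv, results/phases.csv, results/bottom_events.csv\n")
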