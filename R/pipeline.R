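#' Run the sensor pipeline on one deployment
#'
#' Executes every processing stage in order: swimming effort, prey-encounter
#' detection, zero-offset correction + dive segmentation (with drift
#' flagging), 1 Hz orientation, and the per-dive and per-transit-phase
#' covariate tables.
#'
#' @param deployment a `ses_deployment` (see [simulate_deployment()] or
#'   [read_deployment()]).
#' @return list with `effort`, `events`, `segmentation`, `orientation`,
#'   `dive_table`, `phase_table`.
#' @export
analyze_deployment <- function(deployment) {
  effort <- swimming_effort(deployment$acc[, 2], deployment$fs_acc)
  events <- detect_pee(deployment$acc, deployment$fs_acc)
  seg <- segment_deployment(deployment$depth, effort)
  orient <- orientation_series(deployment$acc, deployment$mag,
                               deployment$fs_acc)
  dive_table <- build_dive_table(deployment, seg, events, orient, effort)
  phase_table <- build_phase_table(deployment, seg, effort)
  list(effort = effort, events = events, segmentation = seg,
       orientation = orient, dive_table = dive_table,
       phase_table = phase_table)
}

# The shared covariate set of the dive-level models.
dive_model_covariates <- function() {
  c(bottom_median_depth_m = 1L, bottom_vertical_extent_m = 1L,
    pct_bottom_wiggle = 1L, pct_bottom_step = 1L,
    mean_pitch_descent_deg = 1L, mean_pitch_ascent_deg = 1L,
    var_pitch_bottom = 1L, var_heading_bottom = 1L)
}

#' Fit the five dive-behaviour models
#'
#' Fits the pipeline's model suite on a per-dive covariate table (and a
#' per-transit-phase table): day and night negative-binomial models of the
#' bottom prey-encounter count with a log bottom-duration offset (1a, 1b),
#' a mixed model of surface horizontal speed (2), a variable-dispersion
#' beta regression of dive efficiency (3), and a mixed model of transit
#' phase duration with phase-type interactions (4). Covariates are
#' standardized, tables optionally thinned to one dive in `thin_k`, the
#' backward-AIC + polynomial-escalation selection applied, mixed models
#' refitted with REML, and a goodness-of-fit summary table returned.
#'
#' @param dive_table per-dive covariate table (possibly several individuals
#'   row-bound together).
#' @param phase_table per-transit-phase table.
#' @param thin_k thinning factor (default 1: no thinning; the original
#'   analysis used 10 on multi-month records).
#' @param select run the selection procedure (default) or fit the full
#'   models directly.
#' @return list with `fits` (named list of `ses_fit`) and `summary`
#'   (data.frame with one row per model: family, n, D2, R2m, R2c,
#'   Pearson2).
#' @export
run_five_models <- function(dive_table, phase_table, thin_k = 1L,
                            select = TRUE) {
  covs <- dive_model_covariates()
  if (length(unique(dive_table$individual)) < 2) {
    stop("run_five_models needs dives from at least two individuals ",
         "(random and fixed individual intercepts are part of the models)")
  }
  tab <- standardize_covariates(dive_table, names(covs))
  tab <- thin_every_k(tab, thin_k)
  ind <- "individual"

  fits <- list()
  one <- function(spec, data) if (select) select_model(spec, data) else
    fit_model(spec, data, REML = TRUE)

  for (dn in c("day", "night")) {
    sub <- tab[!is.na(tab$daynight) & tab$daynight == dn, ]
    fits[[if (dn == "day") "1a" else "1b"]] <-
      one(model_spec("negbin", "bottom_pee_count", covs,
                     offset = "bottom_duration_min",
                     individual = ind), sub)
  }
  sub2 <- tab[!is.na(tab$surface_speed_m_s), ]
  fits[["2"]] <- one(model_spec("lmm", "surface_speed_m_s", covs,
                                individual = "individual"), sub2)
  sub3 <- tab[tab$dive_efficiency > 0 & tab$dive_efficiency < 1, ]
  fits[["3"]] <- one(model_spec("beta", "dive_efficiency", covs,
                                individual = ind), sub3)
  ptab <- standardize_covariates(phase_table,
                                 c("phase_max_depth_m", "mean_effort"))
  ptab$phase <- factor(ptab$phase, levels = c("descent", "ascent"))
  fits[["4"]] <- one(model_spec("lmm", "duration_s",
                                c(phase_max_depth_m = 1L, mean_effort = 1L),
                                individual = "individual",
                                interaction_factor = "phase"), ptab)

  summ <- do.call(rbind, lapply(names(fits), function(m) {
    f <- fits[[m]]
    data.frame(
      model = m, family = f$family, n = f$n,
      D2 = if (f$family == "negbin") deviance_explained(f) else NA_real_,
      R2m = if (f$family == "lmm") nakagawa_r2(f)[["R2m"]] else NA_real_,
      R2c = if (f$family == "lmm") nakagawa_r2(f)[["R2c"]] else NA_real_,
      Pearson2 = pearson2(f))
  }))
  list(fits = fits, summary = summ)
}
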