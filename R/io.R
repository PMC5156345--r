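#' Write a deployment to delimited-text files
#'
#' One CSV per stream (`depth.csv`, `acc.csv`, `mag.csv`, `gps.csv`) with
#' epoch-second time columns, a truth interval table (`truth.csv`: stream,
#' start_s, end_s, label) when truth is supplied, and a `manifest.csv`
#' recording the configuration and seed.
#'
#' @param deployment a `ses_deployment`.
#' @param dir output directory (created if needed).
#' @param truth optional `ses_truth`.
#' @return `dir`, invisibly.
#' @export
write_deployment <- function(deployment, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n1 <- length(deployment$depth)
  utils::write.csv(data.frame(time_s = seq_len(n1) - 1,
                              depth_m = deployment$depth),
                   file.path(dir, "depth.csv"), row.names = FALSE)
  fs <- deployment$fs_acc
  t16 <- (seq_len(nrow(deployment$acc)) - 1) / fs
  utils::write.csv(data.frame(time_s = t16, x = deployment$acc[, 1],
                              y = deployment$acc[, 2],
                              z = deployment$acc[, 3]),
                   file.path(dir, "acc.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = t16, x = deployment$mag[, 1],
                              y = deployment$mag[, 2],
                              z = deployment$mag[, 3]),
                   file.path(dir, "mag.csv"), row.names = FALSE)
  utils::write.csv(deployment$gps, file.path(dir, "gps.csv"),
                   row.names = FALSE)
  cfg <- deployment$config
  scal <- vapply(cfg, function(v) length(v) == 1 && is.atomic(v), logical(1))
  mani <- data.frame(key = names(cfg)[scal],
                     value = vapply(cfg[scal], function(v)
                       format(v, digits = 15), character(1)))
  mani <- rbind(mani, data.frame(
    key = names(cfg)[!scal],
    value = vapply(cfg[!scal], function(v)
      paste(format(v, digits = 15), collapse = ";"), character(1))))
  utils::write.csv(mani, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    tr <- rbind(
      data.frame(stream = "dive", start_s = truth$dives$start_s,
                 end_s = truth$dives$end_s,
                 label = ifelse(truth$dives$drift, "drift", "dive")),
      data.frame(stream = "phase", start_s = truth$phases$start_s,
                 end_s = truth$phases$end_s, label = truth$phases$phase),
      if (nrow(truth$events)) {
        data.frame(stream = "event", start_s = truth$events$start_s,
                   end_s = truth$events$end_s, label = truth$events$kind)
      },
      if (nrow(truth$pee)) {
        data.frame(stream = "pee", start_s = truth$pee$start_s,
                   end_s = truth$pee$end_s, label = truth$pee$phase)
      })
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a deployment from delimited-text files
#'
#' Inverse of [write_deployment()] for the sensor streams (config metadata
#' is restored for the scalar keys the pipeline needs).
#'
#' @param dir directory holding `depth.csv`, `acc.csv`, `mag.csv`,
#'   `gps.csv` and `manifest.csv`.
#' @return a `ses_deployment`.
#' @export
read_deployment <- function(dir) {
  depth <- utils::read.csv(file.path(dir, "depth.csv"))
  acc <- utils::read.csv(file.path(dir, "acc.csv"))
  mag <- utils::read.csv(file.path(dir, "mag.csv"))
  gps <- utils::read.csv(file.path(dir, "gps.csv"))
  mani <- utils::read.csv(file.path(dir, "manifest.csv"),
                          colClasses = "character")
  val <- function(key, default = NA) {
    v <- mani$value[mani$key == key]
    if (length(v)) v else default
  }
  fs <- round(nrow(acc) / nrow(depth))
  structure(list(
    depth = depth$depth_m, fs_depth = 1L,
    acc = as.matrix(acc[, c("x", "y", "z")]),
    mag = as.matrix(mag[, c("x", "y", "z")]),
    fs_acc = fs, gps = gps,
    start_time = as.POSIXct(val("start_time", "2014-11-05 00:00:00"),
                            tz = "UTC"),
    individual = val("individual", "unknown"),
    config = NULL), class = "ses_deployment")
}
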