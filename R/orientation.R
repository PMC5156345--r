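#' Pitch and roll from unit-norm static acceleration
#'
#' Body axes follow the logger convention: X longitudinal (positive
#' forward), Y lateral (positive rightward), Z vertical (positive
#' downward). A stationary, level logger reads (0, 0, +1) g, so the static
#' acceleration vector is the unit "down" direction expressed in the body
#' frame, and with the North-East-Down earth frame:
#' pitch = -asin(sx) (positive nose-up, in \[-90, 90\] degrees) and
#' roll = atan2(sy, sz) (positive right-side-down, in (-180, 180\]).
#'
#' @param static n x 3 matrix of unit-norm static acceleration, e.g. from
#'   [static_acceleration()].
#' @param tol tolerance on the unit-norm precondition.
#' @return data.frame with columns `pitch` and `roll` in degrees.
#' @export
pitch_roll <- function(static, tol = 1e-6) {
  static <- as.matrix(static)
  stopifnot(ncol(static) == 3)
  nrm <- sqrt(rowSums(static^2))
  if (any(abs(nrm - 1) > tol)) {
    stop("static acceleration is not unit-norm; run static_acceleration() first")
  }
  sx <- pmin(pmax(static[, 1], -1), 1)
  data.frame(pitch = rad2deg(-asin(sx)),
             roll = rad2deg(atan2(static[, 2], static[, 3])))
}

#' Tilt-compensated heading
#'
#' Rotates the body-frame magnetic vector back to the horizontal plane using
#' roll then pitch, and takes the heading as `atan2(-my_h, mx_h)` mapped to
#' \[0, 360) degrees, clockwise from magnetic north. The magnetometer input
#' should be low-pass filtered with the same 0.20 Hz specification used for
#' static acceleration. Heading is undefined (NA, flagged) where the
#' de-rotated horizontal component is negligible or pitch is +/-90 degrees.
#'
#' @param pitch,roll orientation angles in degrees (equal length).
#' @param mag n x 3 matrix of (filtered) body-frame magnetometer readings.
#' @param tol horizontal component threshold as a fraction of the local
#'   field norm below which heading is flagged undefined.
#' @return numeric vector of headings in degrees, `NA` where undefined, with
#'   attribute `"flagged"` listing undefined samples.
#' @export
tilt_compensated_heading <- function(pitch, roll, mag, tol = 1e-6) {
  mag <- as.matrix(mag)
  stopifnot(ncol(mag) == 3, length(pitch) == nrow(mag),
            length(roll) == nrow(mag))
  th <- deg2rad(pitch)
  ph <- deg2rad(roll)
  # undo roll about X, then pitch about Y (inverse of the body rotation)
  my_r <- mag[, 2] * cos(ph) - mag[, 3] * sin(ph)
  mz_r <- mag[, 2] * sin(ph) + mag[, 3] * cos(ph)
  mx_h <- mag[, 1] * cos(th) + mz_r * sin(th)
  my_h <- my_r
  fieldn <- sqrt(rowSums(mag^2))
  horiz <- sqrt(mx_h^2 + my_h^2)
  bad <- which(horiz < tol * pmax(fieldn, .Machine$double.eps) |
                 abs(abs(pitch) - 90) < 1e-9)
  hd <- wrap360(rad2deg(atan2(-my_h, mx_h)))
  hd[bad] <- NA_real_
  attr(hd, "flagged") <- bad
  hd
}

#' Circular mean of angles
#'
#' `atan2(mean(sin), mean(cos))`, returned in degrees. For heading-like
#' inputs the result is wrapped to \[0, 360); otherwise it is returned in
#' (-180, 180\]. The mean is undefined (NA) when the resultant length is
#' below `1e-12` (e.g. antipodal pairs).
#'
#' @param angles angles in degrees (NAs dropped).
#' @param wrap if `TRUE`, map the result to \[0, 360).
#' @return circular mean in degrees, or `NA` if undefined.
#' @export
circular_mean <- function(angles, wrap = FALSE) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("circular_mean of empty input")
  a <- deg2rad(angles)
  s <- mean(sin(a))
  c <- mean(cos(a))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  out <- rad2deg(atan2(s, c))
  if (wrap) wrap360(out) else out
}

#' Circular variance of angles
#'
#' `1 - Rbar` where `Rbar` is the mean resultant length; 0 for identical
#' angles, 1 for maximal dispersion (e.g. an antipodal pair). Always in
#' \[0, 1\] and invariant to rotating all angles by a constant.
#'
#' @param angles angles in degrees (NAs dropped).
#' @return scalar in \[0, 1\].
#' @export
circular_variance <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("circular_variance of empty input")
  a <- deg2rad(angles)
  1 - sqrt(mean(sin(a))^2 + mean(cos(a))^2)
}

# Circular block mean: average 16 Hz angles to 1 Hz without wrap artefacts.
block_circular_mean <- function(angles_deg, fs) {
  n <- length(angles_deg) %/% fs
  m <- matrix(deg2rad(angles_deg[seq_len(n * fs)]), nrow = fs)
  rad2deg(atan2(colMeans(sin(m), na.rm = TRUE), colMeans(cos(m), na.rm = TRUE)))
}

#' Orientation series at 1 Hz
#'
#' Full posture pipeline: static acceleration (0.20 Hz low-pass, unit norm)
#' -> pitch/roll; magnetometer low-passed with the same filter -> tilt
#' compensated heading; all three angles block-averaged (circular mean) from
#' 16 Hz to 1 Hz for alignment with the depth channel.
#'
#' @param accel n x 3 acceleration matrix (g) at `fs_hz`.
#' @param mag n x 3 magnetometer matrix at `fs_hz`.
#' @param fs_hz sampling rate, default 16 Hz.
#' @return data.frame at 1 Hz with columns `pitch`, `roll`, `heading`
#'   (degrees; heading in \[0, 360)).
#' @export
orientation_series <- function(accel, mag, fs_hz = 16) {
  sa <- static_acceleration(accel, fs_hz)
  pr <- pitch_roll(sa)
  spec <- filter_spec("lowpass", 0.20, fs_hz)
  magf <- apply_filter(as.matrix(mag), spec)
  hd <- tilt_compensated_heading(pr$pitch, pr$roll, magf)
  data.frame(pitch = block_circular_mean(pr$pitch, fs_hz),
             roll = block_circular_mean(pr$roll, fs_hz),
             heading = wrap360(block_circular_mean(hd, fs_hz)))
}
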