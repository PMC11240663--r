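#' Decompose raw acceleration into static and dynamic components
#'
#' Per axis, the dynamic (movement) component is the 1.75--22.05 Hz band-pass
#' of the raw signal and the static (gravitational) component is its 1.78 Hz
#' low-pass. Filters are 4th-order Butterworth applied forward and backward
#' (zero phase), so samples stay time-aligned with behaviour labels. VeDBA and
#' the tilt angles of the static gravity vector are computed alongside.
#'
#' If `fs <= 2 * band_high` the upper band edge is clipped to 0.99 x Nyquist
#' with a warning. The first and last `ceiling(fs)` samples are flagged as
#' edge samples (filter start-up transients).
#'
#' @param trace An [accel_trace()].
#' @param band_low,band_high Band-pass edges for the dynamic component, Hz.
#' @param lowpass Low-pass cut-off for the static component, Hz.
#' @param order Butterworth order (applied twice by the zero-phase pass).
#' @return An object of class `filtered_trace`: the parent trace plus
#'   `dyn_x/y/z`, `stat_x/y/z`, `vedba`, `roll`, `pitch`, `yaw` and a logical
#'   `edge` flag per sample.
#' @export
decompose <- function(trace, band_low = 1.75, band_high = 22.05,
                      lowpass = 1.78, order = 4) {
  stopifnot(inherits(trace, "accel_trace"))
  fs <- trace$fs
  nyq <- fs / 2
  if (band_high >= nyq) {
    warning(sprintf("band-pass upper edge %.4g Hz >= Nyquist %.4g Hz; clipping to %.4g Hz",
                    band_high, nyq, 0.99 * nyq))
    band_high <- 0.99 * nyq
  }
  n <- length(trace$x)
  # filtfilt needs runway: 3x the band-pass filter length (2*order+1 coeffs)
  min_n <- 3 * (2 * order + 1)
  if (n < min_n)
    abort_typed("TraceTooShort", sprintf("need >= %d samples for filtering, got %d", min_n, n))
  bp <- signal::butter(order, c(band_low, band_high) / nyq, type = "pass")
  lp <- signal::butter(order, lowpass / nyq, type = "low")
  dyn <- lapply(trace[c("x", "y", "z")], function(a) signal::filtfilt(bp, a))
  sta <- lapply(trace[c("x", "y", "z")], function(a) signal::filtfilt(lp, a))
  ang <- tilt_angles(sta$x, sta$y, sta$z)
  edge <- rep(FALSE, n)
  k <- min(ceiling(fs), n)
  edge[seq_len(k)] <- TRUE
  edge[seq.int(n - k + 1L, n)] <- TRUE
  structure(
    list(parent = trace,
         dyn_x = dyn$x, dyn_y = dyn$y, dyn_z = dyn$z,
         stat_x = sta$x, stat_y = sta$y, stat_z = sta$z,
         vedba = vedba(dyn$x, dyn$y, dyn$z),
         roll = ang$roll, pitch = ang$pitch, yaw = ang$yaw,
         edge = edge),
    class = "filtered_trace")
}

#' @export
print.filtered_trace <- function(x, ...) {
  cat(sprintf("<filtered_trace> bird %s: %d samples @ %g Hz; mean VeDBA %.3f g\n",
              x$parent$bird_id, length(x$vedba), x$parent$fs, mean(x$vedba)))
  invisible(x)
}

#' Vectorial dynamic body acceleration
#'
#' Per-sample Euclidean norm of the three dynamic components,
#' `sqrt(dx^2 + dy^2 + dz^2)` -- the standard scalar activity proxy.
#'
#' @param dyn_x,dyn_y,dyn_z Dynamic acceleration series in g, equal length.
#' @return Non-negative numeric series in g.
#' @export
vedba <- function(dyn_x, dyn_y, dyn_z) {
  if (length(dyn_y) != length(dyn_x) || length(dyn_z) != length(dyn_x))
    abort_typed("LengthMismatch", "vedba inputs must have equal length")
  sqrt(dyn_x^2 + dyn_y^2 + dyn_z^2)
}

#' Tilt angles of the gravity vector
#'
#' Computed from the static (gravitational) components:
#' `roll = atan(Y / sqrt(X^2 + Z^2))`, `yaw = atan(Z / sqrt(Y^2 + X^2))`, and
#' by axis symmetry `pitch = atan(X / sqrt(Y^2 + Z^2))`. When a denominator is
#' zero the angle is +/- pi/2 by the sign of the numerator, and 0 when the
#' numerator is also zero.
#'
#' @param stat_x,stat_y,stat_z Static acceleration series in g, equal length.
#' @return List with numeric series `roll`, `pitch`, `yaw` in radians, each in
#'   `[-pi/2, pi/2]`.
#' @export
tilt_angles <- function(stat_x, stat_y, stat_z) {
  if (length(stat_y) != length(stat_x) || length(stat_z) != length(stat_x))
    abort_typed("LengthMismatch", "tilt_angles inputs must have equal length")
  ang1 <- function(num, d1, d2) {
    den <- sqrt(d1^2 + d2^2)
    out <- atan(num / den)                      # den 0, num != 0 -> atan(+-Inf) = +-pi/2
    out[den == 0 & num == 0] <- 0
    out
  }
  list(roll  = ang1(stat_y, stat_x, stat_z),
       pitch = ang1(stat_x, stat_y, stat_z),
       yaw   = ang1(stat_z, stat_y, stat_x))
}
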