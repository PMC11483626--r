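# Geometry and dynamics of resolved contours: Savitzky-Golay smoothing,
# Frenet-Serret tangent angle and curvature, end-to-end distance, per-frame
# statistics, tangent-angle kymographs, and FFT power spectra.

#' Smooth a pixel contour with a Savitzky-Golay filter
#'
#' The x and y coordinate sequences are filtered independently; point count
#' is unchanged and edges are handled by the filter's polynomial edge
#' matrices. Contours shorter than the window shrink the window to the
#' largest valid odd value (with a warning).
#'
#' @param contour a `pixel_contour` (n x 2, (row, col)) or any n x 2 point
#'   matrix.
#' @param window odd smoothing window (default 11).
#' @param polyorder polynomial order (default 3), must be < window.
#' @return object of class `smooth_curve`: list with `points` (n x 2
#'   real (x, y)), `window`, `polyorder`.
#' @export
smooth_contour <- function(contour, window = 11, polyorder = 3) {
  m <- unclass(as.matrix(contour))
  n <- nrow(m)
  # pixel_contour stores (row, col); emit (x, y) = (col, row)
  is_rc <- inherits(contour, "pixel_contour") ||
    identical(colnames(m), c("row", "col"))
  xy <- if (is_rc) cbind(x = m[, 2], y = m[, 1]) else cbind(x = m[, 1], y = m[, 2])
  if (window > n) {
    window <- max(1, n - (1 - n %% 2))
    if (window %% 2 == 0) window <- window - 1
    warning(sprintf("contour shorter than window; window shrunk to %d", window))
  }
  stopifnot(window %% 2 == 1)
  if (window == 1 || window <= polyorder) {
    pts <- xy
  } else {
    pts <- cbind(
      x = signal::sgolayfilt(xy[, 1], p = polyorder, n = window),
      y = signal::sgolayfilt(xy[, 2], p = polyorder, n = window)
    )
  }
  structure(list(points = pts, window = window, polyorder = polyorder),
            class = "smooth_curve")
}

curve_points <- function(curve) {
  if (inherits(curve, "smooth_curve")) curve$points
  else if (inherits(curve, "pixel_contour")) {
    m <- unclass(curve); cbind(x = m[, 2], y = m[, 1])
  } else as.matrix(curve)
}

#' Tangent angle and curvature along a curve
#'
#' Derivatives are taken by central finite differences (one-sided at the
#' ends). The tangent angle `psi = atan2(y', x')` is unwrapped along arc
#' length; the unsigned curvature is
#' `|x' y'' - y' x''| / (x'^2 + y'^2)^(3/2)` in 1/pixel.
#'
#' @param curve a `smooth_curve` (or n x 2 (x, y) matrix) with >= 3 points.
#' @return list with `psi` (radians, unwrapped) and `kappa` (1/px), one
#'   value per (deduplicated) point.
#' @export
tangent_and_curvature <- function(curve) {
  pts <- curve_points(curve)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  stopifnot(n >= 3)
  d1 <- function(v) {
    c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
  }
  d2 <- function(v) {
    c(v[3] - 2 * v[2] + v[1],
      v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)],
      v[n] - 2 * v[n - 1] + v[n - 2])
  }
  xp <- d1(pts[, 1]); yp <- d1(pts[, 2])
  xpp <- d2(pts[, 1]); ypp <- d2(pts[, 2])
  psi <- unwrap_angles(atan2(yp, xp))
  kappa <- abs(xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  list(psi = psi, kappa = kappa)
}

# Unwrap a radian sequence so successive jumps stay within (-pi, pi].
unwrap_angles <- function(theta) {
  d <- diff(theta)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  theta - 2 * pi * jumps
}

# Temporal unwrapping that tolerates isolated outliers: each value is
# placed on the 2*pi branch nearest the median of the last three unwrapped
# values, so a single corrupted frame cannot shift the remainder of the
# series by a full turn.
unwrap_angles_robust <- function(theta) {
  out <- theta
  for (i in seq_along(theta)[-1]) {
    ref <- median(out[max(1, i - 3):(i - 1)])
    out[i] <- theta[i] + 2 * pi * round((ref - theta[i]) / (2 * pi))
  }
  out
}

#' End-to-end distance of a curve
#'
#' Euclidean distance between the first (clamped) and last (free) points.
#'
#' @param curve a `smooth_curve`, `pixel_contour` or n x 2 matrix.
#' @return distance in pixels.
#' @export
end_to_end_distance <- function(curve) {
  pts <- curve_points(curve)
  stopifnot(nrow(pts) >= 2)
  sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
}

#' One-sided amplitude spectrum of a uniformly sampled time series
#'
#' The mean is subtracted, the FFT taken, and the one-sided amplitude
#' spectrum returned on the frequency grid `k / (N * dt)`.
#'
#' @param series numeric vector (>= 4 samples).
#' @param dt_s sampling interval in seconds.
#' @return data.frame with `freq_hz` and `amplitude`.
#' @export
power_spectrum <- function(series, dt_s) {
  n <- length(series)
  stopifnot(n >= 4, dt_s > 0, all(is.finite(series)))
  z <- fft(series - mean(series))
  half <- floor(n / 2)
  amp <- Mod(z[1:(half + 1)]) / n
  # double the interior bins (energy split between +/- frequencies)
  if (half >= 1) {
    last <- if (n %% 2 == 0) half else half + 1
    amp[2:last] <- 2 * amp[2:last]
  }
  data.frame(freq_hz = (0:half) / (n * dt_s), amplitude = amp)
}

#' Per-frame statistics of a resolved track
#'
#' Smooths every resolved contour and reports arc length, tip angle (the
#' unwrapped tangent angle at the free end), and end-to-end distance.
#' Lengths are in micrometers when `pixel_size_um` is given, otherwise in
#' pixels; the tip-angle series is additionally unwrapped in time.
#'
#' @param track a [track_series()] result.
#' @param pixel_size_um optional micrometers per pixel.
#' @param window,polyorder smoothing parameters for [smooth_contour()].
#' @param subtract_base subtract the frame-wise base tangent angle from the
#'   tip angle (default `FALSE`: absolute image-frame angle).
#' @return data.frame with `frame`, `length`, `tip_angle_rad`,
#'   `end_to_end` (one row per resolved frame); attribute `length_unit`.
#' @export
track_stats <- function(track, pixel_size_um = NULL, window = 11,
                        polyorder = 3, subtract_base = FALSE) {
  stopifnot(inherits(track, "filament_track"))
  scale <- if (is.null(pixel_size_um)) 1 else pixel_size_um
  rows <- list()
  for (k in seq_len(track$n_frames)) {
    ct <- track$contours[[k]]
    if (is.null(ct)) next
    sc <- smooth_contour(ct, window = window, polyorder = polyorder)
    tc <- tangent_and_curvature(sc)
    tip <- tc$psi[length(tc$psi)]
    if (subtract_base) tip <- tip - tc$psi[1]
    rows[[length(rows) + 1L]] <- data.frame(
      frame = k,
      length = curve_arc_length(sc$points) * scale,
      tip_angle_rad = tip,
      end_to_end = end_to_end_distance(sc) * scale
    )
  }
  out <- do.call(rbind, rows)
  # the arc-length unwrapped tangent carries +/- 2*pi winding when the
  # contour loops; reduce to the principal direction before unwrapping the
  # series in time
  wrapped <- atan2(sin(out$tip_angle_rad), cos(out$tip_angle_rad))
  out$tip_angle_rad <- unwrap_angles_robust(wrapped)
  attr(out, "length_unit") <- if (is.null(pixel_size_um)) "px" else "um"
  out
}

#' Tangent-angle kymograph of a track
#'
#' Resamples each resolved contour's unwrapped tangent angle onto a fixed
#' number of arc-length bins, yielding a frames x bins matrix suitable for
#' kymograph display or CSV export.
#'
#' @param track a [track_series()] result.
#' @param n_bins number of arc-length bins.
#' @param window,polyorder smoothing parameters.
#' @return numeric matrix (rows = frames, `NA` rows for unresolved
#'   frames).
#' @export
tangent_kymograph <- function(track, n_bins = 50, window = 11,
                              polyorder = 3) {
  stopifnot(inherits(track, "filament_track"))
  out <- matrix(NA_real_, track$n_frames, n_bins)
  for (k in seq_len(track$n_frames)) {
    ct <- track$contours[[k]]
    if (is.null(ct)) next
    sc <- smooth_contour(ct, window = window, polyorder = polyorder)
    tc <- tangent_and_curvature(sc)
    s <- c(0, cumsum(sqrt(rowSums(diff(sc$points)^2))))
    s <- s[seq_along(tc$psi)]
    grid <- seq(0, s[length(s)], length.out = n_bins)
    out[k, ] <- approx(s, tc$psi, xout = grid, rule = 2)$y
  }
  out
}
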