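# Synthetic image formation for clamped oscillating filaments: a parametric
# traveling-wave contour generator, rasterization to one-pixel skeletons,
# dilation + Gaussian PSF rendering, and Gaussian / salt-and-pepper noise at
# controlled SNR.

#' Parameters of the traveling-wave filament generator
#'
#' Describes a single filament clamped at its base whose tangent angle
#' carries a traveling wave, emulating the wave-like oscillations of
#' end-pinned filaments driven by surface motors.
#'
#' @param length_um filament length in micrometers (5-50 supported).
#' @param pixel_size_um micrometers per pixel.
#' @param amplitude_rad peak tangent-angle amplitude at the free tip
#'   (radians); the amplitude ramps linearly from 0 at the clamped base.
#' @param wavelength_um spatial wavelength of the traveling wave (um).
#' @param period_s temporal oscillation period (s).
#' @param n_frames number of frames.
#' @param dt_s frame interval (s).
#' @param base_xy optional clamp position `c(x, y)` in pixels (1-based);
#'   when `NULL` the canvas is auto-sized and the base placed so the whole
#'   series fits with a 10-pixel margin.
#' @param base_angle_rad clamp orientation (radians, image frame).
#' @param bias_rad static tangent-angle bias at the tip (radians), ramped
#'   linearly from the base like the wave amplitude. A nonzero bias bends
#'   the mean shape to one side, as motor-driven clamped filaments beat
#'   around a bowed mean shape rather than a straight line; it also breaks
#'   the half-period mirror symmetry of the pure wave, so scalar readouts
#'   such as the end-to-end distance oscillate at the beat period rather
#'   than its half.
#' @param arc_step_px arc-length sampling interval of the generated curves.
#' @return object of class `wave_params`.
#' @export
wave_params <- function(length_um = 20, pixel_size_um = 0.1,
                        amplitude_rad = 1.5, wavelength_um = 15,
                        period_s = 200, n_frames = 120, dt_s = 10,
                        base_xy = NULL, base_angle_rad = 0,
                        bias_rad = 0.8, arc_step_px = 0.25) {
  p <- list(
    length_um = length_um, pixel_size_um = pixel_size_um,
    amplitude_rad = amplitude_rad, wavelength_um = wavelength_um,
    period_s = period_s, n_frames = as.integer(n_frames), dt_s = dt_s,
    base_xy = base_xy, base_angle_rad = base_angle_rad,
    bias_rad = bias_rad, arc_step_px = arc_step_px
  )
  num <- unlist(p[c("length_um", "pixel_size_um", "amplitude_rad",
                    "wavelength_um", "period_s", "n_frames", "dt_s",
                    "base_angle_rad", "bias_rad", "arc_step_px")])
  if (any(!is.finite(num))) stop("wave_params: all parameters must be finite")
  if (p$length_um <= 0) stop("wave_params: length_um must be > 0")
  if (p$pixel_size_um <= 0) stop("wave_params: pixel_size_um must be > 0")
  if (p$n_frames < 1L) stop("wave_params: n_frames must be >= 1")
  if (p$arc_step_px <= 0) stop("wave_params: arc_step_px must be > 0")
  class(p) <- "wave_params"
  p
}

#' Ordered sub-pixel filament contour
#'
#' @param points n x 2 numeric matrix of (x, y) positions in pixels
#'   (x = column, y = row, 1-based, sub-pixel real values). The first point
#'   is the clamped base.
#' @param arc_step_px sampling interval along arc length.
#' @return object of class `filament_curve`.
#' @export
filament_curve <- function(points, arc_step_px = 0.25) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2, all(is.finite(points)))
  colnames(points) <- c("x", "y")
  structure(list(points = points, arc_step_px = arc_step_px),
            class = "filament_curve")
}

#' Arc length of a curve (sum of chord lengths)
#' @param curve a `filament_curve` or n x 2 point matrix.
#' @return length in pixels.
#' @export
curve_arc_length <- function(curve) {
  pts <- if (inherits(curve, "filament_curve")) curve$points else as.matrix(curve)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Generate a beating clamped filament as per-frame ground-truth curves
#'
#' The tangent angle along arc length s at frame time t is
#' `psi(s, t) = base_angle_rad + B(s) + A(s) * sin(2*pi*(s/lambda - t/T))`
#' with amplitude ramp `A(s) = amplitude_rad * s / L` and static bend
#' `B(s) = bias_rad * s / L`, so the base is clamped both in position and
#' orientation. Positions follow by cumulative integration of
#' `(cos psi, sin psi)`, which makes every frame's curve inextensible
#' (arc length `length_um / pixel_size_um` pixels).
#'
#' @param params a [wave_params()] object.
#' @param shape optional canvas `c(nrow, ncol)`; curves leaving this canvas
#'   raise an error. When `NULL` the canvas is auto-sized (bounding box of
#'   all frames plus a 10-pixel margin).
#' @return list of [filament_curve()], one per frame, with attributes
#'   `shape` (canvas) and `params`.
#' @export
generate_beating_filament <- function(params, shape = NULL) {
  stopifnot(inherits(params, "wave_params"))
  L <- params$length_um / params$pixel_size_um
  lambda <- params$wavelength_um / params$pixel_size_um
  ds <- params$arc_step_px
  s <- seq(0, L, by = ds)
  if (s[length(s)] < L) s <- c(s, L)
  ramp <- params$amplitude_rad * s / L
  bias <- params$bias_rad * s / L
  frames <- vector("list", params$n_frames)
  for (k in seq_len(params$n_frames)) {
    t <- (k - 1L) * params$dt_s
    psi <- params$base_angle_rad + bias +
      ramp * sin(2 * pi * (s / lambda - t / params$period_s))
    # midpoint rule on the unit tangent keeps chord spacing ~ds
    psi_mid <- (psi[-1] + psi[-length(psi)]) / 2
    dstep <- diff(s)
    x <- cumsum(c(0, cos(psi_mid) * dstep))
    y <- cumsum(c(0, sin(psi_mid) * dstep))
    frames[[k]] <- cbind(x = x, y = y)
  }
  allx <- unlist(lapply(frames, function(m) m[, 1]))
  ally <- unlist(lapply(frames, function(m) m[, 2]))
  margin <- 10
  if (is.null(params$base_xy)) {
    x0 <- margin + 1 - min(allx)
    y0 <- margin + 1 - min(ally)
  } else {
    x0 <- params$base_xy[1]
    y0 <- params$base_xy[2]
  }
  if (is.null(shape)) {
    shape <- c(
      ceiling(max(ally) + y0 + margin),
      ceiling(max(allx) + x0 + margin)
    )
  }
  curves <- lapply(frames, function(m) {
    m[, 1] <- m[, 1] + x0
    m[, 2] <- m[, 2] + y0
    if (min(m) < 1 || max(m[, 1]) > shape[2] || max(m[, 2]) > shape[1]) {
      stop("generated curve exits the canvas; enlarge `shape` or move base_xy")
    }
    filament_curve(m, arc_step_px = ds)
  })
  attr(curves, "shape") <- shape
  attr(curves, "params") <- params
  curves
}

#' Rasterize a curve to a one-pixel-wide 8-connected skeleton
#'
#' Dense arc-length samples are rounded to pixel centers and the resulting
#' set thinned to single-pixel width; every curve point lies within sqrt(2)
#' pixels of a lit pixel.
#'
#' @param curve a [filament_curve()].
#' @param shape raster dimensions `c(nrow, ncol)`.
#' @return logical matrix (the skeleton raster).
#' @export
rasterize_skeleton <- function(curve, shape) {
  pts <- if (inherits(curve, "filament_curve")) curve$points else as.matrix(curve)
  rows <- round(pts[, 2]); cols <- round(pts[, 1])
  if (min(rows) < 1 || min(cols) < 1 || max(rows) > shape[1] ||
      max(cols) > shape[2]) {
    stop("curve points fall outside the raster shape")
  }
  mask <- matrix(FALSE, shape[1], shape[2])
  mask[cbind(rows, cols)] <- TRUE
  if (sum(mask) <= 2) return(mask)
  sk <- clean_staircase(thin_mask(mask))
  # thinning can erode the very tips of the curve; reconnect the rounded
  # first and last curve points to the nearest remaining skeleton pixel
  for (tip in list(c(rows[1], cols[1]),
                   c(rows[length(rows)], cols[length(cols)]))) {
    if (!sk[tip[1], tip[2]]) {
      lit <- which(sk, arr.ind = TRUE, useNames = FALSE)
      near <- lit[which.min((lit[, 1] - tip[1])^2 + (lit[, 2] - tip[2])^2), ]
      n <- max(abs(tip - near)) + 1L
      seg <- cbind(round(seq(near[1], tip[1], length.out = n)),
                   round(seq(near[2], tip[2], length.out = n)))
      sk[seg] <- TRUE
    }
  }
  clean_staircase(sk)
}

#' Render a skeleton as a microscopy-like grayscale image
#'
#' The binary skeleton is dilated by a diamond-shaped structuring element of
#' radius 2 (the 13-pixel footprint `|di| + |dj| <= 2`), convolved with a
#' normalized 3 x 3 Gaussian point-spread kernel of sigma = 2, and rescaled
#' to `[0, 1]`.
#'
#' @param skeleton binary matrix.
#' @return numeric matrix in `[0, 1]`.
#' @export
render_image <- function(skeleton) {
  mask <- skeleton != 0
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  dil <- dilate_plus(dilate_plus(mask))
  img <- conv_kernel(dil * 1, gaussian_kernel_3x3(sigma = 2))
  img / max(img)
}

gaussian_kernel_3x3 <- function(sigma = 2) {
  d <- -1:1
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Convert SNR in decibels to a linear power ratio
#' @param snr_db SNR in dB.
#' @return `10^(snr_db / 10)`.
#' @export
snr_db_to_linear <- function(snr_db) {
  stopifnot(is.finite(snr_db))
  10^(snr_db / 10)
}

#' Add Gaussian noise at a target SNR
#'
#' Signal power is the variance of the input intensities; noise power is
#' `P_signal / snr_linear` and the additive noise is
#' `sqrt(P_noise) * N(0, 1)` per pixel.
#'
#' @param image numeric matrix.
#' @param snr_db target SNR in decibels.
#' @param seed optional integer seed (reproducible noise).
#' @return noisy image (same shape; values may leave `[0, 1]`).
#' @export
add_gaussian_noise <- function(image, snr_db, seed = NULL) {
  stopifnot(all(is.finite(image)), is.finite(snr_db))
  p_signal <- var(as.vector(image))
  if (p_signal == 0) return(image)
  p_noise <- p_signal / snr_db_to_linear(snr_db)
  if (!is.null(seed)) set.seed(seed)
  image + sqrt(p_noise) * rnorm(length(image))
}

#' Add salt-and-pepper noise
#'
#' A fraction `density` of pixels is replaced by 0 or 1 with equal
#' probability.
#'
#' @param image numeric matrix.
#' @param density fraction of corrupted pixels in `[0, 1]`.
#' @param seed optional integer seed.
#' @return corrupted image.
#' @export
add_salt_pepper_noise <- function(image, density, seed = NULL) {
  stopifnot(density >= 0, density <= 1)
  if (density == 0) return(image)
  if (!is.null(seed)) set.seed(seed)
  hit <- runif(length(image)) < density
  vals <- ifelse(runif(length(image)) < 0.5, 0, 1)
  image[hit] <- vals[hit]
  image
}

#' Synthesize a full noisy frame series from wave parameters
#'
#' Runs the generator, rasterizes per-frame ground-truth skeletons, renders
#' each through the dilation + PSF model, and adds noise.
#'
#' @param params a [wave_params()] object.
#' @param snr_db SNR in dB for Gaussian noise, or `NULL` for noiseless
#'   output.
#' @param noise `"gaussian"` or `"saltpepper"`.
#' @param density salt-and-pepper density (used only for
#'   `noise = "saltpepper"`).
#' @param seed integer seed for the noise stream.
#' @param shape optional canvas.
#' @return list of frames; each frame is a list with `truth_curve`,
#'   `truth_skeleton`, `image`, `snr_db`. Attribute `shape` carries the
#'   canvas.
#' @export
synthesize_series <- function(params, snr_db = NULL,
                              noise = c("gaussian", "saltpepper"),
                              density = 0.05, seed = NULL, shape = NULL) {
  noise <- match.arg(noise)
  curves <- generate_beating_filament(params, shape = shape)
  shape <- attr(curves, "shape")
  frames <- vector("list", length(curves))
  for (k in seq_along(curves)) {
    skel <- rasterize_skeleton(curves[[k]], shape)
    img <- render_image(skel)
    frame_seed <- if (is.null(seed)) NULL else seed + k
    applied_snr <- NA_real_
    if (!is.null(snr_db)) {
      if (noise == "gaussian") {
        img <- add_gaussian_noise(img, snr_db, seed = frame_seed)
        applied_snr <- snr_db
      } else {
        img <- add_salt_pepper_noise(img, density, seed = frame_seed)
        p_sig <- var(as.vector(render_image(skel)))
        p_noi <- var(as.vector(img - render_image(skel)))
        applied_snr <- if (p_noi > 0) 10 * log10(p_sig / p_noi) else Inf
      }
    }
    frames[[k]] <- list(
      truth_curve = curves[[k]], truth_skeleton = skel,
      image = img, snr_db = applied_snr
    )
  }
  attr(frames, "shape") <- shape
  attr(frames, "params") <- params
  frames
}

#' Write a synthesized series as a TIFF stack plus ground-truth CSV
#'
#' The TIFF stack holds frames in acquisition order (intensities clipped to
#' `[0, 1]`); the CSV has columns `frame, point_index, x, y` with 0-based
#' pixel coordinates (x = column, y = row).
#'
#' @param frames output of [synthesize_series()].
#' @param tiff_path output TIFF path.
#' @param truth_csv_path optional output CSV path for the ground truth.
#' @return invisibly, the paths written.
#' @export
write_synthetic_stack <- function(frames, tiff_path, truth_csv_path = NULL) {
  imgs <- lapply(frames, function(f) pmin(pmax(f$image, 0), 1))
  tiff::writeTIFF(imgs, tiff_path)
  if (!is.null(truth_csv_path)) {
    tabs <- lapply(seq_along(frames), function(k) {
      pts <- frames[[k]]$truth_curve$points
      data.frame(frame = k, point_index = seq_len(nrow(pts)) - 1L,
                 x = pts[, 1] - 1, y = pts[, 2] - 1)
    })
    write.csv(do.call(rbind, tabs), truth_csv_path, row.names = FALSE)
  }
  invisible(c(tiff_path, truth_csv_path))
}
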