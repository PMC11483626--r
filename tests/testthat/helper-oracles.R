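# Independent brute-force oracles and small geometric fixtures used across
# the test files. The oracles deliberately avoid the package's own dynamic
# programs: alignment scores are computed by exhaustive enumeration of
# monotone lattice paths.

# All monotone lattice paths from (1,1) to (n,m) with steps (+1,0), (0,+1),
# (+1,+1); returns a list of k x 2 index matrices.
all_monotone_paths <- function(n, m) {
  paths <- list()
  recurse <- function(i, j, acc) {
    acc <- rbind(acc, c(i, j))
    if (i == n && j == m) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
  }
  recurse(1, 1, matrix(numeric(0), 0, 2))
  paths
}

pt_dist <- function(a, i, b, j) {
  sqrt(sum((a[i, ] - b[j, ])^2))
}

# Brute-force DTW: minimum over monotone alignments of the summed local
# Euclidean costs.
brute_dtw <- function(a, b) {
  paths <- all_monotone_paths(nrow(a), nrow(b))
  min(vapply(paths, function(p) {
    sum(vapply(seq_len(nrow(p)), function(k) pt_dist(a, p[k, 1], b, p[k, 2]),
               numeric(1)))
  }, numeric(1)))
}

# Brute-force discrete Frechet: minimum over monotone couplings of the
# maximum pointwise distance.
brute_frechet <- function(a, b) {
  paths <- all_monotone_paths(nrow(a), nrow(b))
  min(vapply(paths, function(p) {
    max(vapply(seq_len(nrow(p)), function(k) pt_dist(a, p[k, 1], b, p[k, 2]),
               numeric(1)))
  }, numeric(1)))
}

# O(n^2) pixel matching oracle.
brute_match <- function(detected, truth, tol) {
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(detected))) {
    dmin <- Inf
    for (j in seq_len(nrow(truth))) {
      dmin <- min(dmin, pt_dist(detected, i, truth, j))
    }
    if (dmin <= tol) tp <- tp + 1L else fp <- fp + 1L
  }
  fn <- 0L
  for (j in seq_len(nrow(truth))) {
    dmin <- Inf
    for (i in seq_len(nrow(detected))) {
      dmin <- min(dmin, pt_dist(truth, j, detected, i))
    }
    if (dmin > tol) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Brute-force branch detection: 3x3 window sum (center included) >= 4.
brute_branch_pixels <- function(mask) {
  out <- NULL
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (!mask[r, c]) next
      rs <- max(1, r - 1):min(nrow(mask), r + 1)
      cs <- max(1, c - 1):min(ncol(mask), c + 1)
      if (sum(mask[rs, cs]) >= 4) out <- rbind(out, c(r, c))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# --- geometric fixtures -----------------------------------------------------

# Rasterize a dense (x, y) polyline into a thinned skeleton mask.
raster_from_points <- function(pts, shape) {
  rasterize_skeleton(filament_curve(pts, arc_step_px = 0.25), shape)
}

# Resample a parametric curve to ~uniform arc-length spacing.
dense_curve <- function(fx, fy, t_range, n = 4000, step = 0.25) {
  t <- seq(t_range[1], t_range[2], length.out = n)
  x <- fx(t); y <- fy(t)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  grid <- seq(0, s[length(s)], by = step)
  cbind(x = approx(s, x, grid)$y, y = approx(s, y, grid)$y)
}

# Single-crossing "alpha" curve with two free tails; crossing at (x0, y0).
make_alpha_points <- function(x0 = 45, y0 = 50, scale = 10, t_max = 1.7) {
  dense_curve(function(t) x0 + scale * (t^2 - 1),
              function(t) y0 + scale * 0.9 * t * (t^2 - 1),
              c(-t_max, t_max))
}

# Figure-of-eight style fixture: alpha curve rasterized plus its skeleton.
make_alpha_fixture <- function() {
  pts <- make_alpha_points()
  shape <- c(100, 100)
  mask <- raster_from_points(pts, shape)
  list(points = pts, shape = shape, mask = mask, skel = skeleton(mask))
}

# Prolate cycloid: x = v t - a sin t, y = y0 - a cos t; one transversal
# self-crossing per period when a > v. Two periods -> two crossings.
make_two_crossing_points <- function(v = 4, a = 9, y0 = 30) {
  dense_curve(function(t) 15 + v * t + a * sin(t),
              function(t) y0 + a * cos(t),
              c(-1.2, 4 * pi + 1.2))
}

# A beating series with knots: curves, canvas and rasterized skeletons.
make_knotted_series <- function(n_frames = 20, amplitude_rad = 3.5,
                                snr_db = NULL, seed = NULL, ...) {
  p <- wave_params(length_um = 20, pixel_size_um = 0.1,
                   amplitude_rad = amplitude_rad, wavelength_um = 15,
                   period_s = 200, n_frames = n_frames, dt_s = 10, ...)
  if (is.null(snr_db)) {
    curves <- generate_beating_filament(p)
    shape <- attr(curves, "shape")
    list(params = p, curves = curves, shape = shape,
         skeletons = lapply(curves, function(cv)
           skeleton(rasterize_skeleton(cv, shape))))
  } else {
    frames <- synthesize_series(p, snr_db = snr_db, seed = seed)
    list(params = p, frames = frames, shape = attr(frames, "shape"),
         curves = lapply(frames, `[[`, "truth_curve"))
  }
}

truth_rc <- function(curve) {
  pts <- if (inherits(curve, "filament_curve")) curve$points else curve
  cbind(pts[, 2], pts[, 1])
}
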