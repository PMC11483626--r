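# Accuracy metrics against ground truth: tolerance-based pixel matching and
# Dice index, discrete Frechet distance, and per-pixel position error.

#' Match detected pixels to ground truth within a tolerance
#'
#' True positives are detected pixels within `tolerance_px` (Euclidean) of
#' some truth pixel; the remaining detected pixels are false positives;
#' truth pixels with no detected pixel within tolerance are false
#' negatives.
#'
#' @param detected n x 2 matrix of detected (row, col) pixels (may be
#'   empty).
#' @param truth m x 2 matrix of ground-truth pixels (may be empty).
#' @param tolerance_px distance threshold in pixels (default 2, chosen to
#'   match the point-spread footprint of the image-formation model).
#' @return object of class `match_counts`: list with `tp`, `fp`, `fn`,
#'   `tolerance_px`.
#' @export
match_pixels <- function(detected, truth, tolerance_px = 2) {
  stopifnot(tolerance_px > 0)
  detected <- as.matrix(detected); truth <- as.matrix(truth)
  if (nrow(detected) == 0) {
    counts <- list(tp = 0L, fp = 0L, fn = nrow(truth),
                   tolerance_px = tolerance_px)
  } else if (nrow(truth) == 0) {
    counts <- list(tp = 0L, fp = nrow(detected), fn = 0L,
                   tolerance_px = tolerance_px)
  } else {
    d_det <- nearest_distances(detected, truth)
    d_tru <- nearest_distances(truth, detected)
    counts <- list(
      tp = sum(d_det <= tolerance_px),
      fp = sum(d_det > tolerance_px),
      fn = sum(d_tru > tolerance_px),
      tolerance_px = tolerance_px
    )
  }
  structure(counts, class = "match_counts")
}

#' Dice index from match counts
#'
#' `2 * TP / (2 * TP + FP + FN)`. The degenerate all-zero case (empty
#' detection against empty truth) is defined as 1 and reported with a
#' message so batch summaries stay total.
#'
#' @param counts a [match_pixels()] result (or list with `tp`, `fp`, `fn`).
#' @return score in `[0, 1]`.
#' @export
dice_index <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp == 0 && fp == 0 && fn == 0) {
    message("dice_index: no pixels on either side; returning 1")
    return(1)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Discrete Frechet distance between two ordered curves
#'
#' The minimum over monotone couplings of the maximum pointwise Euclidean
#' distance ("dog-leash" distance); sensitive to point ordering, so a curve
#' and its reversal generally differ. Duplicate curves score exactly 0.
#'
#' @param curve_a,curve_b non-empty n x 2 point matrices (consistent
#'   coordinate convention).
#' @return nonnegative distance.
#' @export
frechet_distance <- function(curve_a, curve_b) {
  a <- unclass(as.matrix(curve_a)); b <- unclass(as.matrix(curve_b))
  stopifnot(nrow(a) > 0, nrow(b) > 0, ncol(a) == 2, ncol(b) == 2)
  .frechet_cpp(matrix(as.numeric(a), nrow(a)), matrix(as.numeric(b), nrow(b)))
}

#' Per-pixel position error of a detection against ground truth
#'
#' For each detected pixel, the Euclidean distance to the nearest ground
#' truth pixel; the summary mean and SD mirror Gaussian fits to error
#' histograms.
#'
#' @param detected n x 2 matrix of detected pixels.
#' @param truth non-empty m x 2 matrix of truth pixels.
#' @return numeric vector of distances with attributes `mean` and `sd`.
#' @export
position_error <- function(detected, truth) {
  truth <- as.matrix(truth)
  stopifnot(nrow(truth) > 0)
  detected <- as.matrix(detected)
  if (nrow(detected) == 0) {
    warning("position_error: no detected pixels")
    return(structure(numeric(0), mean = NA_real_, sd = NA_real_))
  }
  d <- nearest_distances(detected, truth)
  structure(d, mean = mean(d), sd = sd(d))
}

#' Benchmark a track against ground-truth curves
#'
#' Scores each resolved frame against its ground-truth contour with the
#' tolerance-based Dice index, the discrete Frechet distance, and the
#' position-error summary.
#'
#' @param track a [track_series()] result.
#' @param truth_curves list of per-frame truth contours
#'   ([filament_curve()] objects or n x 2 (x, y) matrices).
#' @param tolerance_px Dice matching tolerance.
#' @return data.frame with `frame, dice, frechet_px, mean_err_px,
#'   sd_err_px`.
#' @export
benchmark_track <- function(track, truth_curves, tolerance_px = 2) {
  stopifnot(inherits(track, "filament_track"),
            length(truth_curves) >= track$n_frames)
  rows <- list()
  for (k in seq_len(track$n_frames)) {
    ct <- track$contours[[k]]
    if (is.null(ct)) next
    tc <- truth_curves[[k]]
    pts <- if (inherits(tc, "filament_curve")) tc$points else as.matrix(tc)
    truth_rc <- cbind(pts[, 2], pts[, 1])   # (row, col)
    det_rc <- unclass(ct)
    counts <- match_pixels(det_rc, truth_rc, tolerance_px)
    err <- position_error(det_rc, truth_rc)
    rows[[length(rows) + 1L]] <- data.frame(
      frame = k,
      dice = dice_index(counts),
      frechet_px = frechet_distance(det_rc, truth_rc),
      mean_err_px = attr(err, "mean"),
      sd_err_px = attr(err, "sd")
    )
  }
  do.call(rbind, rows)
}
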