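# Frame segmentation: contrast saturation + median filtering, Otsu
# thresholding, Chan-Vese style active-contour refinement, and medial-axis
# skeletonization with spur pruning.

#' Segmentation parameters
#'
#' @param intensity_threshold normalized threshold in `[0, 1]`, or `"auto"`
#'   to use Otsu's inter-class-variance maximizer.
#' @param ac_iterations active-contour iteration count (0 disables
#'   refinement).
#' @param contraction_bias balloon term; positive values shrink the contour.
#' @param smooth_factor boundary regularization weight.
#' @param saturate_frac intensity fraction clipped at each histogram tail
#'   during preprocessing.
#' @param median_kernel odd median-filter window size.
#' @param prune_len skeleton spurs shorter than this many pixels are
#'   removed.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(intensity_threshold = "auto",
                                ac_iterations = 10,
                                contraction_bias = 0.4,
                                smooth_factor = 0.2,
                                saturate_frac = 0.01,
                                median_kernel = 3,
                                prune_len = 5) {
  if (!identical(intensity_threshold, "auto")) {
    stopifnot(is.numeric(intensity_threshold),
              intensity_threshold >= 0, intensity_threshold <= 1)
  }
  stopifnot(ac_iterations >= 0, median_kernel >= 1, median_kernel %% 2 == 1,
            saturate_frac >= 0, saturate_frac < 0.5, prune_len >= 0)
  structure(list(
    intensity_threshold = intensity_threshold,
    ac_iterations = as.integer(ac_iterations),
    contraction_bias = contraction_bias,
    smooth_factor = smooth_factor,
    saturate_frac = saturate_frac,
    median_kernel = as.integer(median_kernel),
    prune_len = prune_len
  ), class = "segmentation_params")
}

#' Contrast-enhance and denoise a frame
#'
#' Clips intensities at the `saturate_frac` and `1 - saturate_frac`
#' quantiles, rescales linearly to `[0, 1]`, and applies a median filter.
#'
#' @param image numeric matrix.
#' @param params [segmentation_params()].
#' @return numeric matrix in `[0, 1]` (all zeros for a constant input).
#' @export
preprocess_frame <- function(image, params = segmentation_params()) {
  stopifnot(all(is.finite(image)))
  q <- quantile(image, c(params$saturate_frac, 1 - params$saturate_frac),
                names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(image), ncol(image)))
  img <- pmin(pmax(image, q[1]), q[2])
  img <- (img - q[1]) / (q[2] - q[1])
  if (params$median_kernel > 1) {
    img <- EBImage::medianFilter(img, (params$median_kernel - 1L) / 2L)
  }
  img
}

#' Binarize a preprocessed frame
#'
#' Thresholds at Otsu's level (or a user override) and retains the largest
#' 8-connected foreground component.
#'
#' @param image preprocessed numeric matrix in `[0, 1]`.
#' @param params [segmentation_params()].
#' @return logical mask.
#' @export
binarize_frame <- function(image, params = segmentation_params()) {
  thr <- if (identical(params$intensity_threshold, "auto")) {
    EBImage::otsu(image, range = c(0, 1))
  } else {
    params$intensity_threshold
  }
  mask <- image > thr
  if (!any(mask)) {
    stop("segmentation failed: empty foreground after thresholding")
  }
  largest_component(mask)
}

#' Refine a binary mask with a Chan-Vese style active contour
#'
#' Minimizes the two-phase piecewise-constant (Chan-Vese) energy by
#' synchronous discrete updates: each iteration recomputes the inside and
#' outside mean intensities and reassigns pixels by the data term plus a
#' Potts-style smoothness penalty (`smooth_factor`) and a constant balloon
#' pressure (`contraction_bias`, positive shrinks). Both regularizers are
#' scaled by the squared contrast between phases so behavior is invariant
#' to intensity scaling. If evolution empties the mask, the seed is
#' returned unchanged.
#'
#' @param image numeric matrix.
#' @param seed_mask non-empty logical mask.
#' @param params [segmentation_params()].
#' @return refined logical mask (never empty).
#' @export
refine_chan_vese <- function(image, seed_mask, params = segmentation_params()) {
  stopifnot(any(seed_mask))
  u <- seed_mask
  for (it in seq_len(params$ac_iterations)) {
    if (!any(u) || all(u)) break
    c1 <- mean(image[u])
    c2 <- mean(image[!u])
    contrast2 <- (c1 - c2)^2
    if (contrast2 == 0) break
    n_in <- moore_neighbor_count(u)
    data_term <- (image - c1)^2 - (image - c2)^2
    smooth_term <- params$smooth_factor * contrast2 * (8 - 2 * n_in) / 8
    bias_term <- params$contraction_bias * contrast2
    u_new <- (data_term + smooth_term + bias_term) < 0
    if (!any(u_new)) break
    if (identical(u_new, u)) {
      u <- u_new
      break
    }
    u <- u_new
  }
  if (!any(u)) return(seed_mask)
  largest_component(u)
}

#' Skeletonize a mask to a one-pixel contour
#'
#' Thins the mask to single-pixel width, prunes spur branches shorter than
#' `prune_len`, and returns a [skeleton] object.
#'
#' @param mask non-empty logical mask (single connected component).
#' @param params [segmentation_params()] (for `prune_len`).
#' @param extend_tips extend the skeleton from its endpoints along the
#'   local direction while still inside `mask`. The medial axis of a
#'   rounded band stops about half a band-width short of the true filament
#'   tip; the extension recovers it.
#' @return object of class `skeleton`; see [skeleton()].
#' @export
skeletonize_mask <- function(mask, params = segmentation_params(),
                             extend_tips = TRUE) {
  stopifnot(any(mask))
  sk <- clean_staircase(thin_mask(mask))
  sk <- prune_spurs(sk, params$prune_len)
  if (!any(sk)) stop("segmentation failed: skeleton is empty after pruning")
  if (extend_tips) sk <- extend_skeleton_tips(sk, mask)
  skeleton(sk)
}

# Extend each skeleton endpoint along the direction of its last few pixels,
# adding pixels while they stay inside the support mask.
extend_skeleton_tips <- function(sk, mask, lookback = 5L, max_extend = 10L) {
  counts <- moore_neighbor_count(sk)
  ends <- which(sk & counts == 1L, arr.ind = TRUE, useNames = FALSE)
  for (e in seq_len(nrow(ends))) {
    ord <- geodesic_order(sk, ends[e, ])
    k <- min(lookback + 1L, nrow(ord))
    if (k < 2) next
    dirv <- ord[1, ] - ord[k, ]
    nv <- sqrt(sum(dirv^2))
    if (nv == 0) next
    dirv <- dirv / nv
    pos <- as.numeric(ord[1, ])
    for (step in seq_len(max_extend)) {
      pos <- pos + dirv
      rc <- round(pos)
      if (rc[1] < 1 || rc[2] < 1 || rc[1] > nrow(mask) || rc[2] > ncol(mask)) break
      if (!mask[rc[1], rc[2]]) break
      sk[rc[1], rc[2]] <- TRUE
    }
  }
  clean_staircase(sk)
}

# Remove terminal spurs shorter than prune_len: walk from each endpoint; if
# a branch pixel is met within prune_len steps, delete the walked pixels.
prune_spurs <- function(mask, prune_len) {
  if (prune_len <= 0) return(mask)
  repeat {
    counts <- moore_neighbor_count(mask)
    branch <- mask & counts >= 3
    if (!any(branch)) break
    ends <- which(mask & counts == 1, arr.ind = TRUE, useNames = FALSE)
    removed_any <- FALSE
    for (e in seq_len(nrow(ends))) {
      path <- walk_from_endpoint(mask, branch, ends[e, ], prune_len)
      if (!is.null(path)) {
        mask[path] <- FALSE
        removed_any <- TRUE
        break # masks changed; recompute neighbor counts
      }
    }
    if (!removed_any) break
  }
  # a pruned spur can leave its junction pixel as a one-pixel bump
  clean_staircase(mask)
}

# Walk along the skeleton from an endpoint; return the pixel indices of the
# spur if a branch pixel is reached in < max_len steps, else NULL.
walk_from_endpoint <- function(mask, branch, start, max_len) {
  nr <- nrow(mask)
  cur <- start
  prev <- c(NA_integer_, NA_integer_)
  path <- integer(0)
  for (step in seq_len(max_len)) {
    if (branch[cur[1], cur[2]]) return(path)
    path <- c(path, cur[1] + (cur[2] - 1L) * nr)
    nb_r <- cur[1] + MOORE_OFFSETS[, 1]
    nb_c <- cur[2] + MOORE_OFFSETS[, 2]
    ok <- nb_r >= 1 & nb_r <= nr & nb_c >= 1 & nb_c <= ncol(mask)
    nb_r <- nb_r[ok]; nb_c <- nb_c[ok]
    lit <- mask[cbind(nb_r, nb_c)] &
      !(nb_r == prev[1] & nb_c == prev[2] & !is.na(prev[1]))
    lit[is.na(lit)] <- FALSE
    nxt <- which(lit)
    if (length(nxt) == 0) return(NULL)     # isolated chain, not a spur
    if (length(nxt) > 1) {
      # reached the junction neighborhood: prefer a branch pixel
      br <- which(branch[cbind(nb_r[nxt], nb_c[nxt])])
      nxt <- if (length(br) > 0) nxt[br[1]] else nxt[1]
    }
    prev <- cur
    cur <- c(nb_r[nxt], nb_c[nxt])
  }
  NULL
}

#' Segment one grayscale frame to a skeleton
#'
#' Convenience wrapper: [preprocess_frame()] then [binarize_frame()],
#' [refine_chan_vese()], and [skeletonize_mask()].
#'
#' @param image numeric matrix.
#' @param params [segmentation_params()].
#' @param refine apply the active-contour refinement (set `FALSE` for a
#'   threshold-only segmentation, e.g. for method comparisons).
#' @return a [skeleton()] object.
#' @export
segment_frame <- function(image, params = segmentation_params(),
                          refine = TRUE) {
  pre <- preprocess_frame(image, params)
  mask <- binarize_frame(pre, params)
  if (refine && params$ac_iterations > 0) {
    mask <- refine_chan_vese(pre, mask, params)
  }
  skeletonize_mask(mask, params)
}
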