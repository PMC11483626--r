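# Internal raster helpers shared across modules. Images and masks are base R
# matrices indexed (row, col), 1-based; pixel lists are n x 2 integer matrices
# with columns (row, col).

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) == 0 || length(cs) == 0) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

MOORE_OFFSETS <- cbind(
  dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

# Count of lit Moore neighbors for every pixel (center excluded).
moore_neighbor_count <- function(mask) {
  m <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(MOORE_OFFSETS))) {
    m <- m + shift_mat(mask * 1L, MOORE_OFFSETS[k, 1], MOORE_OFFSETS[k, 2])
  }
  m
}

mask_to_pixels <- function(mask) {
  which(mask != 0, arr.ind = TRUE, useNames = FALSE)
}

pixels_to_mask <- function(pixels, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  if (nrow(pixels) > 0) mask[pixels] <- TRUE
  mask
}

# 8-connected component labels over a logical mask; 0 = background.
# Components are found on the pixel adjacency graph via igraph.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(labels)
  id_of <- integer(nr * nc)
  id_of[idx] <- seq_along(idx)
  edges <- integer(0)
  # forward offsets only; each undirected adjacency counted once
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    both <- mask & shift_mat(mask, -off[1], -off[2], fill = FALSE)
    from <- which(both)
    if (length(from) == 0) next
    to <- from + off[1] + off[2] * nr
    edges <- c(edges, rbind(id_of[from], id_of[to]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

# Retain the largest 8-connected component of a mask.
largest_component <- function(mask) {
  labels <- label_components(mask)
  if (max(labels) <= 1L) return(mask)
  keep <- which.max(tabulate(labels[labels > 0]))
  labels == keep
}

# Binary dilation with the radius-1 diamond (plus-shaped) structuring element.
dilate_plus <- function(mask) {
  mask |
    shift_mat(mask, 1, 0, FALSE) | shift_mat(mask, -1, 0, FALSE) |
    shift_mat(mask, 0, 1, FALSE) | shift_mat(mask, 0, -1, FALSE)
}

# Convolve with an arbitrary small odd-sized kernel, zero padding.
conv_kernel <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) / 2L
  kc <- (ncol(kernel) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * shift_mat(m, (i - 1L) - kr, (j - 1L) - kc)
    }
  }
  out
}

# Euclidean distance from each row of `a` to the nearest row of `b`
# (both n x 2 numeric matrices). Sizes here are small (skeleton-scale),
# so the cross-distance is computed blockwise to bound memory.
nearest_distances <- function(a, b, block = 2048L) {
  stopifnot(nrow(b) > 0)
  out <- numeric(nrow(a))
  if (nrow(a) == 0) return(out)
  b1 <- b[, 1]; b2 <- b[, 2]
  for (start in seq(1L, nrow(a), by = block)) {
    idx <- start:min(start + block - 1L, nrow(a))
    d2 <- outer(a[idx, 1], b1, "-")^2 + outer(a[idx, 2], b2, "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}
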