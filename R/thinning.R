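# Zhang-Suen thinning to a one-pixel-wide, 8-connected skeleton.
# Used both for medial-axis style skeletonization of segmentation masks and
# to reduce rounded dense curve samples to single-pixel rasters.

# Neighborhood layout (clockwise from north):
#   P9 P2 P3
#   P8 P1 P4
#   P7 P6 P5
zs_neighbors <- function(mask) {
  list(
    p2 = shift_mat(mask, 1, 0, FALSE),   # north neighbor value at center: row-1 -> shift down
    p3 = shift_mat(mask, 1, -1, FALSE),
    p4 = shift_mat(mask, 0, -1, FALSE),
    p5 = shift_mat(mask, -1, -1, FALSE),
    p6 = shift_mat(mask, -1, 0, FALSE),
    p7 = shift_mat(mask, -1, 1, FALSE),
    p8 = shift_mat(mask, 0, 1, FALSE),
    p9 = shift_mat(mask, 1, 1, FALSE)
  )
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Iterative Zhang-Suen thinning; the result is 8-connected and at most one
#' pixel wide (in the Zhang-Suen sense). Connectivity of each component is
#' preserved.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of the same shape.
#' @export
thin_mask <- function(mask) {
  m <- mask != 0
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- zs_neighbors(m)
      b <- Reduce(`+`, lapply(nb, function(x) x * 1L))
      seq8 <- with(nb, list(p2, p3, p4, p5, p6, p7, p8, p9, p2))
      a <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        a <- a + ((!seq8[[k]]) & seq8[[k + 1]]) * 1L
      }
      if (step == 1) {
        cond <- with(nb, (!(p2 & p4 & p6)) & (!(p4 & p6 & p8)))
      } else {
        cond <- with(nb, (!(p2 & p4 & p8)) & (!(p2 & p6 & p8)))
      }
      del <- m & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Yokoi connectivity number for 8-connectivity from the neighbor values
# p2..p9 (clockwise from north). C8 == 1 marks an 8-simple pixel: deleting
# it does not change the local topology.
yokoi_c8 <- function(p) {
  q <- lapply(p, function(x) 1L - x * 1L)
  ring <- list(q$p2, q$p3, q$p4, q$p5, q$p6, q$p7, q$p8, q$p9, q$p2, q$p3)
  total <- 0L
  for (k in c(1L, 3L, 5L, 7L)) { # p2, p4, p6, p8
    total <- total + ring[[k]] - ring[[k]] * ring[[k + 1]] * ring[[k + 2]]
  }
  total
}

# Remove redundant staircase pixels left by thinning so that spurious
# branch points disappear while the skeleton geometry is preserved. Two
# kinds of 8-simple pixels (Yokoi C8 == 1) are deleted: pixels with three
# or more neighbors (the only ones that can fire the Moore branch
# criterion), and two-neighbor corners directly adjacent to such a pixel
# (cutting the corner resolves the neighboring pseudo-branch). Plain
# staircase corners elsewhere are kept, so the contour is not eroded.
# Deletion is sequential: each candidate is re-verified on the current
# mask.
clean_staircase <- function(mask) {
  neighbor_count_at <- function(r, c) {
    rs <- max(1, r - 1):min(nrow(mask), r + 1)
    cs <- max(1, c - 1):min(ncol(mask), c + 1)
    sum(mask[rs, cs]) - 1L
  }
  repeat {
    nb <- zs_neighbors(mask)
    b <- Reduce(`+`, lapply(nb, function(x) x * 1L))
    c8 <- yokoi_c8(nb)
    branchy <- mask & b >= 3L
    near_branchy <- moore_neighbor_count(branchy) > 0L
    cand <- which(mask & c8 == 1L & (b >= 3L | (b == 2L & near_branchy)))
    if (length(cand) == 0) break
    nr <- nrow(mask); nc <- ncol(mask)
    removed <- FALSE
    for (idx in cand) {
      r <- ((idx - 1L) %% nr) + 1L
      c <- ((idx - 1L) %/% nr) + 1L
      if (r <= 1 || r >= nr || c <= 1 || c >= nc) next
      p <- list(
        p2 = mask[r - 1, c], p3 = mask[r - 1, c + 1], p4 = mask[r, c + 1],
        p5 = mask[r + 1, c + 1], p6 = mask[r + 1, c],
        p7 = mask[r + 1, c - 1], p8 = mask[r, c - 1], p9 = mask[r - 1, c - 1]
      )
      bb <- sum(unlist(p))
      if (yokoi_c8(p) != 1L) next
      ok <- bb >= 3L
      if (!ok && bb == 2L) {
        nbr <- lit_neighbors(mask, r, c)
        ok <- any(vapply(seq_len(nrow(nbr)), function(k) {
          neighbor_count_at(nbr[k, 1], nbr[k, 2]) >= 3L
        }, logical(1)))
      }
      if (ok) {
        mask[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  mask
}
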