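# Skeleton objects, branch-point detection (Moore criterion), geodesic
# ordering of unbranched skeletons, and mapping of branched skeletons to a
# directed graph of branch (Vb) and filament-segment (Vf) vertices.

#' Skeleton object
#'
#' A one-pixel-wide, 8-connected binary contour with derived endpoints and
#' branch classification.
#'
#' @param mask logical matrix with the lit skeleton pixels.
#' @return object of class `skeleton` with fields `mask`, `shape`,
#'   `pixels` (n x 2 (row, col)), `endpoints` (pixels with exactly one
#'   Moore neighbor), `branch_pixels` (Moore-criterion branches) and
#'   `is_branched`.
#' @export
skeleton <- function(mask) {
  mask <- mask != 0
  pixels <- mask_to_pixels(mask)
  if (nrow(pixels) == 0) stop("skeleton: empty mask")
  counts <- moore_neighbor_count(mask)
  endpoints <- which(mask & counts == 1L, arr.ind = TRUE, useNames = FALSE)
  branch <- which(mask & counts >= 3L, arr.ind = TRUE, useNames = FALSE)
  structure(list(
    mask = mask, shape = dim(mask), pixels = pixels,
    endpoints = endpoints, branch_pixels = branch,
    is_branched = nrow(branch) > 0
  ), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf(
    "<skeleton> %d px on %d x %d canvas, %d endpoint(s), %s\n",
    nrow(x$pixels), x$shape[1], x$shape[2], nrow(x$endpoints),
    if (x$is_branched) sprintf("%d branch px", nrow(x$branch_pixels))
    else "unbranched"
  ))
  invisible(x)
}

#' Find branch pixels by the Moore-neighborhood sum criterion
#'
#' A lit pixel is a branch point when the sum of pixel values over its 3 x 3
#' Moore neighborhood (center included, center value 1) is at least 4,
#' i.e. the pixel has three or more lit neighbors.
#'
#' @param skel a [skeleton()] (or logical mask).
#' @return m x 2 integer matrix of (row, col) branch pixels.
#' @export
find_branch_pixels <- function(skel) {
  mask <- if (inherits(skel, "skeleton")) skel$mask else skel != 0
  counts <- moore_neighbor_count(mask)
  which(mask & (counts + 1L) >= 4L, arr.ind = TRUE, useNames = FALSE)
}

#' Find skeleton endpoints
#'
#' Endpoints are lit pixels with exactly one lit Moore neighbor. A closed
#' loop has none (an empty result, not an error).
#'
#' @param skel a [skeleton()] (or logical mask).
#' @return m x 2 integer matrix of (row, col) endpoints.
#' @export
find_endpoints <- function(skel) {
  mask <- if (inherits(skel, "skeleton")) skel$mask else skel != 0
  counts <- moore_neighbor_count(mask)
  which(mask & counts == 1L, arr.ind = TRUE, useNames = FALSE)
}

# Lit Moore neighbors of pixel (r, c).
lit_neighbors <- function(mask, r, c) {
  nb_r <- r + MOORE_OFFSETS[, 1]
  nb_c <- c + MOORE_OFFSETS[, 2]
  ok <- nb_r >= 1 & nb_r <= nrow(mask) & nb_c >= 1 & nb_c <= ncol(mask)
  nb_r <- nb_r[ok]; nb_c <- nb_c[ok]
  lit <- mask[cbind(nb_r, nb_c)]
  cbind(nb_r[lit], nb_c[lit])
}

# Breadth-first geodesic ordering of lit pixels from a start pixel.
# Returns pixels in nondecreasing geodesic distance; within a BFS level,
# ties follow discovery order.
geodesic_order <- function(mask, start) {
  nr <- nrow(mask)
  n <- sum(mask)
  visited <- matrix(FALSE, nr, ncol(mask))
  order_rows <- integer(n); order_cols <- integer(n)
  queue_r <- integer(n); queue_c <- integer(n)
  queue_r[1] <- start[1]; queue_c[1] <- start[2]
  visited[start[1], start[2]] <- TRUE
  head <- 1L; tailp <- 1L; outp <- 0L
  while (head <= tailp) {
    r <- queue_r[head]; c <- queue_c[head]; head <- head + 1L
    outp <- outp + 1L
    order_rows[outp] <- r; order_cols[outp] <- c
    nb <- lit_neighbors(mask, r, c)
    for (k in seq_len(nrow(nb))) {
      if (!visited[nb[k, 1], nb[k, 2]]) {
        visited[nb[k, 1], nb[k, 2]] <- TRUE
        tailp <- tailp + 1L
        queue_r[tailp] <- nb[k, 1]; queue_c[tailp] <- nb[k, 2]
      }
    }
  }
  cbind(order_rows[seq_len(outp)], order_cols[seq_len(outp)])
}

# Walk a thin segment from an entry pixel, visiting each pixel once in path
# order. Rings entered at one pixel are walked all the way around; if the
# entry splits the segment into two arms (side entry), the walk covers arm
# A reversed, the entry, then arm B, so the result is still a path order.
walk_segment <- function(mask, entry) {
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  visited[entry[1], entry[2]] <- TRUE
  walk_arm <- function(from) {
    path <- list()
    cur <- from
    repeat {
      nb <- lit_neighbors(mask, cur[1], cur[2])
      unv <- nb[!visited[nb], , drop = FALSE]
      if (nrow(unv) == 0) break
      if (nrow(unv) > 1) {
        # prefer 4-adjacent continuation to follow the thin path
        d <- abs(unv[, 1] - cur[1]) + abs(unv[, 2] - cur[2])
        unv <- unv[order(d), , drop = FALSE]
      }
      cur <- unv[1, ]
      visited[cur[1], cur[2]] <<- TRUE
      path[[length(path) + 1L]] <- cur
    }
    if (length(path) == 0) NULL else do.call(rbind, path)
  }
  arm1 <- walk_arm(entry)
  arm2 <- walk_arm(entry)
  out <- rbind(
    if (!is.null(arm2)) arm2[rev(seq_len(nrow(arm2))), , drop = FALSE],
    matrix(entry, 1),
    arm1
  )
  out
}

#' Order an unbranched skeleton into a pixel contour
#'
#' Sorts the pixels by increasing geodesic distance from a start endpoint,
#' yielding the ordered contour from the start to the far endpoint.
#'
#' @param skel a [skeleton()] without branch pixels.
#' @param start `c(row, col)` of an endpoint of the skeleton.
#' @return a `pixel_contour`: n x 2 integer matrix (row, col) with class
#'   attribute.
#' @export
order_unbranched <- function(skel, start) {
  stopifnot(inherits(skel, "skeleton"))
  if (skel$is_branched) {
    stop("order_unbranched: skeleton has branch pixels; build a graph instead")
  }
  is_end <- nrow(skel$endpoints) > 0 &&
    any(skel$endpoints[, 1] == start[1] & skel$endpoints[, 2] == start[2])
  if (!is_end) stop("order_unbranched: `start` is not an endpoint")
  ord <- geodesic_order(skel$mask, start)
  if (nrow(ord) != nrow(skel$pixels)) {
    stop("order_unbranched: skeleton is not a single connected component")
  }
  pixel_contour(ord)
}

#' Pixel contour constructor
#' @param points n x 2 integer matrix of ordered (row, col) pixels.
#' @return the matrix with class `pixel_contour`.
#' @export
pixel_contour <- function(points) {
  points <- as.matrix(points)
  colnames(points) <- c("row", "col")
  class(points) <- c("pixel_contour", class(points))
  points
}

# Is segment `i` a bridge between its two branch groups, i.e. does removing
# it disconnect them in the bipartite segment/branch adjacency graph?
is_bridge_segment <- function(edges, i, touching) {
  keep <- edges[edges$vf_label != i, , drop = FALSE]
  if (nrow(keep) == 0) return(TRUE)
  # nodes: f<label> and b<label>
  ig <- igraph::graph_from_data_frame(
    data.frame(from = paste0("f", keep$vf_label),
               to = paste0("b", keep$vb_label)),
    directed = FALSE
  )
  a <- paste0("b", touching[1]); b <- paste0("b", touching[2])
  vs <- igraph::V(ig)$name
  if (!(a %in% vs) || !(b %in% vs)) return(TRUE)
  comp <- igraph::components(ig)$membership
  comp[[a]] != comp[[b]]
}

# Label segment and branch components of a skeleton and enumerate their
# attachments: one edge per segment terminal pixel touching a branch group.
graph_components <- function(mask, branch_mask) {
  seg_mask <- mask & !branch_mask
  b_labels <- label_components(branch_mask)
  f_labels <- label_components(seg_mask)
  edges <- list()
  for (i in seq_len(max(f_labels))) {
    px <- which(f_labels == i, arr.ind = TRUE, useNames = FALSE)
    sub_mask <- pixels_to_mask(px, dim(mask))
    counts <- moore_neighbor_count(sub_mask)
    terminals <- px[counts[px] <= 1L, , drop = FALSE]
    if (nrow(terminals) == 0) terminals <- px # degenerate (cycle segment)
    for (tpix in seq_len(nrow(terminals))) {
      r <- terminals[tpix, 1]; c <- terminals[tpix, 2]
      nb <- lit_neighbors(branch_mask, r, c)
      if (nrow(nb) == 0) next
      touched <- unique(b_labels[nb])
      for (bl in touched) {
        edges[[length(edges) + 1L]] <- data.frame(
          vf_label = i, vb_label = bl, attach_row = r, attach_col = c
        )
      }
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(vf_label = integer(0), vb_label = integer(0),
               attach_row = integer(0), attach_col = integer(0))
  list(b_labels = b_labels, f_labels = f_labels, edges = edges)
}

#' Map a branched skeleton to a directed filament graph
#'
#' Branch pixels are grouped into 8-connected components (branch vertices,
#' `Vb`); the remaining skeleton pixels are grouped into 8-connected
#' components (filament-segment vertices, `Vf`). An edge joins a `Vf` and a
#' `Vb` for every attachment of a segment terminal to the branch group, so
#' a segment whose two ends meet the same branch (a self-merge loop)
#' contributes two parallel edges. Traversal out of the start vertex is
#' one-directional; all other edges are traversable both ways.
#'
#' @param skel a branched [skeleton()].
#' @param branch_pixels branch pixels, e.g. from [find_branch_pixels()];
#'   defaults to the skeleton's own.
#' @param start `c(row, col)` start pixel; must lie on a segment (not a
#'   branch pixel).
#' @return object of class `filament_graph` with `vertices` (list of
#'   `list(id, kind, pixels)`), `edges` (data.frame `vf, vb, attach_row,
#'   attach_col`), `start_vertex`, `end_vertex` (id or `NA`), `start`,
#'   `shape`.
#' @details A single raster crossing is often thinned into two nearby
#'   degree-3 junctions joined by a connector segment that both strands of
#'   the filament share (the same happens when the returning strand runs
#'   tangentially alongside the outgoing one). Such endpoint-free
#'   connectors between two branch groups of degree 3 are absorbed into
#'   one branch vertex, restoring the single-crossing topology; genuine
#'   segments between two transversal (degree-4) crossings are kept.
#' @export
build_filament_graph <- function(skel, branch_pixels = NULL, start) {
  stopifnot(inherits(skel, "skeleton"))
  if (is.null(branch_pixels)) branch_pixels <- skel$branch_pixels
  if (nrow(branch_pixels) == 0) {
    stop("build_filament_graph: skeleton has no branch pixels")
  }
  branch_mask <- pixels_to_mask(branch_pixels, skel$shape)
  endpoint_mask <- pixels_to_mask(skel$endpoints, skel$shape)
  # Absorb shared-run connectors: endpoint-free segments bridging two
  # degree-3 branch groups. Such a segment carries both strands of the
  # filament (a smeared crossing or tangential contact), so the physical
  # path crosses it twice; folding it into one branch vertex restores the
  # single-crossing topology. The bridge requirement keeps loop arcs —
  # which may also join two degree-3 junctions but are cyclically
  # connected — as ordinary segments.
  repeat {
    comp <- graph_components(skel$mask, branch_mask)
    deg <- tabulate(comp$edges$vb_label, nbins = max(comp$b_labels, 1))
    absorbed <- FALSE
    for (i in seq_len(max(comp$f_labels))) {
      px <- which(comp$f_labels == i, arr.ind = TRUE, useNames = FALSE)
      if (any(endpoint_mask[px])) next
      touching <- unique(comp$edges$vb_label[comp$edges$vf_label == i])
      n_edges_i <- sum(comp$edges$vf_label == i)
      if (length(touching) != 2 || n_edges_i != 2) next
      if (!all(deg[touching] == 3)) next
      if (!is_bridge_segment(comp$edges, i, touching)) next
      branch_mask[px] <- TRUE
      absorbed <- TRUE
      break
    }
    if (!absorbed) break
  }
  if (branch_mask[start[1], start[2]]) {
    stop("build_filament_graph: start lies on a branch pixel")
  }
  comp <- graph_components(skel$mask, branch_mask)
  b_labels <- comp$b_labels
  f_labels <- comp$f_labels
  n_b <- max(b_labels); n_f <- max(f_labels)
  vertices <- vector("list", n_b + n_f)
  for (i in seq_len(n_f)) {
    vertices[[i]] <- list(
      id = i, kind = "Vf",
      pixels = which(f_labels == i, arr.ind = TRUE, useNames = FALSE)
    )
  }
  for (i in seq_len(n_b)) {
    vertices[[n_f + i]] <- list(
      id = n_f + i, kind = "Vb",
      pixels = which(b_labels == i, arr.ind = TRUE, useNames = FALSE)
    )
  }
  edges <- data.frame(
    vf = comp$edges$vf_label, vb = n_f + comp$edges$vb_label,
    attach_row = comp$edges$attach_row, attach_col = comp$edges$attach_col
  )
  start_vertex <- f_labels[start[1], start[2]]
  if (start_vertex == 0) {
    stop("build_filament_graph: start pixel is not on a filament segment")
  }
  # end vertex: segment containing the endpoint geodesically farthest from
  # the start (short spur endpoints near the crossing are not the free end)
  end_vertex <- NA_integer_
  eps <- skel$endpoints
  if (nrow(eps) > 0) {
    ord <- geodesic_order(skel$mask, start)
    rank_of <- matrix(NA_integer_, skel$shape[1], skel$shape[2])
    rank_of[ord] <- seq_len(nrow(ord))
    ranks <- rank_of[eps]
    for (k in order(ranks, decreasing = TRUE)) {
      v <- f_labels[eps[k, 1], eps[k, 2]]
      if (v > 0 && v != start_vertex) {
        end_vertex <- v
        break
      }
    }
  }
  structure(list(
    vertices = vertices, edges = edges,
    start_vertex = start_vertex, end_vertex = end_vertex,
    start = start, shape = skel$shape, n_vf = n_f, n_vb = n_b
  ), class = "filament_graph")
}

#' @export
print.filament_graph <- function(x, ...) {
  cat(sprintf(
    "<filament_graph> %d Vf + %d Vb vertices, %d edges, start=Vf%d, end=%s\n",
    x$n_vf, x$n_vb, nrow(x$edges), x$start_vertex,
    if (is.na(x$end_vertex)) "none" else paste0("Vf", x$end_vertex)
  ))
  invisible(x)
}
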