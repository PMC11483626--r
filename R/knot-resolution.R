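# Knot resolution: capped path enumeration over the filament graph, contour
# reconstruction, DTW template matching, and the frame-to-frame tracking
# loop with programmatic manual overrides.

#' Dynamic-time-warping score between two contours
#'
#' Cumulative DTW cost with local cost the Euclidean distance between 2-D
#' points: `D(i,j) = d(i,j) + min(D(i-1,j-1), D(i-1,j), D(i,j-1))` with
#' out-of-range terms infinite; returns `D(n, m)`.
#'
#' @param contour,template non-empty n x 2 point matrices (consistent
#'   coordinate convention; `pixel_contour` objects work directly).
#' @return nonnegative score.
#' @export
dtw_score <- function(contour, template) {
  a <- unclass(as.matrix(contour)); b <- unclass(as.matrix(template))
  stopifnot(nrow(a) > 0, nrow(b) > 0, ncol(a) == 2, ncol(b) == 2)
  .dtw_cost_cpp(matrix(as.numeric(a), nrow(a)), matrix(as.numeric(b), nrow(b)))
}

# Mean nearest-distance from each vertex's pixels to the template points.
vertex_template_scores <- function(graph, template) {
  tpl <- unclass(as.matrix(template))
  vapply(graph$vertices, function(v) {
    mean(nearest_distances(v$pixels, tpl))
  }, numeric(1))
}

#' Select the key vertices closest to the template
#'
#' Scores every graph vertex by the mean Euclidean distance of its pixels
#' to the nearest template point and returns the ids of the three
#' lowest-scoring vertices (all vertices when the graph has fewer than 3).
#' Ties are broken by vertex id.
#'
#' @param graph a [build_filament_graph()] result.
#' @param template a `pixel_contour` (the template contour).
#' @return integer vector of up to 3 vertex ids.
#' @export
select_key_vertices <- function(graph, template) {
  scores <- vertex_template_scores(graph, template)
  ids <- order(scores, seq_along(scores))
  ids[seq_len(min(3L, length(ids)))]
}

#' Enumerate candidate start-to-end paths through a filament graph
#'
#' Depth-first traversal from the start vertex in which a filament vertex
#' (Vf) may be visited at most once, a branch vertex (Vb) may be revisited,
#' and each edge may be traversed at most once per direction. Child
#' expansions are prioritized toward the key vertices (then by template
#' proximity when scores are supplied), and at most `cap` children are
#' retained per expansion. Paths terminate at the end vertex; for graphs
#' without an end vertex a path terminates once every Vf has been visited.
#'
#' @param graph a [build_filament_graph()] result.
#' @param key_vertices vertex ids from [select_key_vertices()] (optional).
#' @param cap beam width per frontier expansion (default 10).
#' @param vertex_scores optional per-vertex template distances used for
#'   child ordering.
#' @param max_paths stop after this many complete paths.
#' @return list of `graph_path` objects (`vertices`, `edges` = row indices
#'   into `graph$edges`, `directions`); error of class
#'   `knottrack_unresolvable` if no admissible path exists.
#' @export
enumerate_paths <- function(graph, key_vertices = integer(0), cap = 10,
                            vertex_scores = NULL, max_paths = 100) {
  edges <- graph$edges
  n_edges <- nrow(edges)
  kind <- vapply(graph$vertices, `[[`, character(1), "kind")
  found <- list()
  # used edge directions: "f2b" (vf -> vb) and "b2f" per edge row
  dfs <- function(cur, visited_vf, used_f2b, used_b2f, vseq, eseq) {
    if (length(found) >= max_paths) return()
    complete <- FALSE
    if (!is.na(graph$end_vertex) && cur == graph$end_vertex) {
      complete <- TRUE
    } else if (is.na(graph$end_vertex) && all(visited_vf)) {
      complete <- TRUE
    }
    if (complete) {
      found[[length(found) + 1L]] <<-
        structure(list(vertices = vseq, edges = eseq), class = "graph_path")
      return()
    }
    if (kind[cur] == "Vf") {
      cand <- which(edges$vf == cur & !used_f2b)
      targets <- edges$vb[cand]
    } else {
      cand <- which(edges$vb == cur & !used_b2f)
      targets <- edges$vf[cand]
      ok <- !visited_vf[targets]
      cand <- cand[ok]; targets <- targets[ok]
    }
    if (length(cand) == 0) {
      # dead end; for endpoint-free graphs a maximal path still counts
      if (is.na(graph$end_vertex) && length(vseq) > 1) {
        found[[length(found) + 1L]] <<-
          structure(list(vertices = vseq, edges = eseq), class = "graph_path")
      }
      return()
    }
    prio <- rep(1, length(cand))
    prio[targets %in% key_vertices] <- 0
    tie <- if (!is.null(vertex_scores)) vertex_scores[targets] else targets
    ord <- order(prio, tie)
    cand <- cand[ord][seq_len(min(cap, length(cand)))]
    targets <- targets[ord][seq_len(min(cap, length(cand)))]
    for (k in seq_along(cand)) {
      e <- cand[k]; nxt <- targets[k]
      u_f2b <- used_f2b; u_b2f <- used_b2f; v_vf <- visited_vf
      if (kind[cur] == "Vf") u_f2b[e] <- TRUE else u_b2f[e] <- TRUE
      if (kind[nxt] == "Vf") v_vf[nxt] <- TRUE
      dfs(nxt, v_vf, u_f2b, u_b2f, c(vseq, nxt), c(eseq, e))
      if (length(found) >= max_paths) return()
    }
  }
  visited0 <- rep(FALSE, length(graph$vertices))
  visited0[graph$start_vertex] <- TRUE
  dfs(graph$start_vertex, visited0,
      rep(FALSE, n_edges), rep(FALSE, n_edges),
      graph$start_vertex, integer(0))
  if (length(found) == 0) {
    stop(structure(
      class = c("knottrack_unresolvable", "error", "condition"),
      list(message = "no admissible path from start to end vertex",
           call = sys.call(-1))
    ))
  }
  found
}

# Shortest 8-connected path within a mask from pixel `from` to pixel `to`
# (both inclusive), by breadth-first search with predecessor tracking.
bfs_path <- function(mask, from, to) {
  nr <- nrow(mask)
  key <- function(p) p[1] + (p[2] - 1L) * nr
  if (all(from == to)) return(matrix(from, 1))
  pred <- integer(nr * ncol(mask))
  visited <- matrix(FALSE, nr, ncol(mask))
  visited[from[1], from[2]] <- TRUE
  queue <- list(from)
  head <- 1L
  while (head <= length(queue)) {
    cur <- queue[[head]]; head <- head + 1L
    nb <- lit_neighbors(mask, cur[1], cur[2])
    for (k in seq_len(nrow(nb))) {
      p <- nb[k, ]
      if (!visited[p[1], p[2]]) {
        visited[p[1], p[2]] <- TRUE
        pred[key(p)] <- key(cur)
        if (all(p == to)) {
          # backtrack
          path <- list(to)
          cur_key <- key(to)
          while (pred[cur_key] != 0L) {
            cur_key <- pred[cur_key]
            r <- ((cur_key - 1L) %% nr) + 1L
            c <- ((cur_key - 1L) %/% nr) + 1L
            path[[length(path) + 1L]] <- c(r, c)
          }
          return(do.call(rbind, rev(path)))
        }
        queue[[length(queue) + 1L]] <- p
      }
    }
  }
  NULL
}

nearest_pixel <- function(pixels, ref) {
  d <- (pixels[, 1] - ref[1])^2 + (pixels[, 2] - ref[2])^2
  pixels[which.min(d), ]
}

#' Convert a graph path to an ordered pixel contour
#'
#' Concatenates the pixels of each visited filament vertex, ordered by
#' geodesic distance from its entry pixel, inserting each traversed branch
#' vertex's pixels (ordered for continuity) at every crossing.
#'
#' @param graph a [build_filament_graph()] result.
#' @param path a `graph_path` from [enumerate_paths()].
#' @return a [pixel_contour()].
#' @export
path_to_contour <- function(graph, path) {
  edges <- graph$edges
  kind <- vapply(graph$vertices, `[[`, character(1), "kind")
  out <- NULL
  entry <- graph$start
  for (k in seq_along(path$vertices)) {
    v <- path$vertices[k]
    px <- graph$vertices[[v]]$pixels
    if (kind[v] == "Vf") {
      if (nrow(px) == 1) {
        seg <- px
      } else {
        sub <- pixels_to_mask(px, graph$shape)
        ep <- entry
        if (!sub[ep[1], ep[2]]) {
          # entry is the attachment pixel; fall back to nearest segment pixel
          d <- (px[, 1] - ep[1])^2 + (px[, 2] - ep[2])^2
          ep <- px[which.min(d), ]
        }
        seg <- walk_segment(sub, ep)
      }
      out <- rbind(out, seg)
      # exit pixel for the next hop: attachment of the outgoing edge
      if (k < length(path$vertices)) {
        e <- edges[path$edges[k], ]
        entry <- c(e$attach_row, e$attach_col)
      }
    } else { # Vb: insert the internal path from entry toward the exit
      ref <- out[nrow(out), ]
      enter_px <- nearest_pixel(px, ref)
      if (k < length(path$vertices)) {
        e <- edges[path$edges[k], ]
        exit_px <- nearest_pixel(px, c(e$attach_row, e$attach_col))
        sub <- pixels_to_mask(px, graph$shape)
        seg <- bfs_path(sub, enter_px, exit_px)
        if (is.null(seg)) seg <- matrix(enter_px, 1)
        entry <- c(e$attach_row, e$attach_col)
      } else {
        sub <- pixels_to_mask(px, graph$shape)
        seg <- geodesic_order(sub, enter_px)
      }
      out <- rbind(out, seg)
    }
  }
  pixel_contour(out)
}

#' Resolve one frame's skeleton into an ordered contour
#'
#' Unbranched skeletons are ordered directly by geodesic distance from the
#' start. Branched skeletons are mapped to a filament graph; candidate
#' paths are enumerated and the contour with the minimal [dtw_score()]
#' against the template is returned (ties broken by enumeration order).
#'
#' @param skel a [skeleton()].
#' @param template the template `pixel_contour` (required when the skeleton
#'   is branched).
#' @param start `c(row, col)` start pixel (an endpoint of the skeleton).
#' @param cap beam width for [enumerate_paths()].
#' @return a [pixel_contour()]; attribute `dtw` carries the selected score
#'   for branched frames.
#' @export
resolve_frame <- function(skel, template = NULL, start, cap = 10) {
  stopifnot(inherits(skel, "skeleton"))
  if (!skel$is_branched) {
    return(order_unbranched(skel, start))
  }
  if (is.null(template)) {
    stop("resolve_frame: branched skeleton requires a template contour")
  }
  graph <- build_filament_graph(skel, start = start)
  scores <- vertex_template_scores(graph, template)
  key <- order(scores, seq_along(scores))[seq_len(min(3L, length(scores)))]
  paths <- enumerate_paths(graph, key_vertices = key, cap = cap,
                           vertex_scores = scores)
  best <- NULL; best_score <- Inf
  for (p in paths) {
    ct <- path_to_contour(graph, p)
    s <- dtw_score(ct, template)
    if (s < best_score) {
      best <- ct
      best_score <- s
    }
  }
  attr(best, "dtw") <- best_score
  best
}

#' Manual override record for a problematic frame
#'
#' Replaces path enumeration on the named frame with an explicit ordered
#' vertex-label sequence (starting at the start vertex), mirroring
#' interactive path correction in a headless, reproducible form.
#'
#' @param frame_index 1-based frame number.
#' @param region_sequence ordered integer vertex ids of the correct path.
#' @return object of class `manual_override`.
#' @export
manual_override <- function(frame_index, region_sequence) {
  structure(list(frame_index = as.integer(frame_index),
                 region_sequence = as.integer(region_sequence)),
            class = "manual_override")
}

# Build a graph_path from an explicit vertex sequence, consuming edge
# directions the same way enumeration does.
path_from_vertex_sequence <- function(graph, vseq) {
  edges <- graph$edges
  if (vseq[1] != graph$start_vertex) {
    stop("manual override path must start at the start vertex")
  }
  used_f2b <- rep(FALSE, nrow(edges)); used_b2f <- rep(FALSE, nrow(edges))
  kind <- vapply(graph$vertices, `[[`, character(1), "kind")
  eseq <- integer(0)
  for (k in seq_len(length(vseq) - 1)) {
    a <- vseq[k]; b <- vseq[k + 1]
    if (kind[a] == "Vf") {
      cand <- which(edges$vf == a & edges$vb == b & !used_f2b)
      if (length(cand) == 0) {
        stop(sprintf("no unused edge from vertex %d to %d", a, b))
      }
      used_f2b[cand[1]] <- TRUE
    } else {
      cand <- which(edges$vb == a & edges$vf == b & !used_b2f)
      if (length(cand) == 0) {
        stop(sprintf("no unused edge from vertex %d to %d", a, b))
      }
      used_b2f[cand[1]] <- TRUE
    }
    eseq <- c(eseq, cand[1])
  }
  structure(list(vertices = vseq, edges = eseq), class = "graph_path")
}

#' Track a filament across a sequence of per-frame skeletons
#'
#' Processes frames in order. Frame 1 must be unbranched (or covered by an
#' override); after each successful resolution the resolved contour becomes
#' the template for the next branched frame. The start point of frame
#' `k + 1` is the endpoint of its skeleton nearest frame `k`'s start.
#' Frames listed in `overrides` bypass enumeration and use the given
#' region sequence verbatim. Frames that cannot be resolved are flagged and
#' skipped; the template is retained.
#'
#' @param skeletons list of per-frame [skeleton()] objects.
#' @param start_rc `c(row, col)` seed for frame 1; defaults to the first
#'   skeleton endpoint.
#' @param cap beam width for path enumeration.
#' @param template_mode `"resolved"` (template is the last successfully
#'   resolved contour) or `"unbranched"` (template only updates on
#'   unbranched frames).
#' @param overrides list of [manual_override()] records.
#' @return object of class `filament_track`: `contours` (list, `NULL`
#'   where unresolved), `resolved` (logical), `dtw_scores`, `branched`.
#' @export
track_series <- function(skeletons, start_rc = NULL, cap = 10,
                         template_mode = c("resolved", "unbranched"),
                         overrides = list()) {
  template_mode <- match.arg(template_mode)
  n <- length(skeletons)
  stopifnot(n >= 1)
  ov_frames <- vapply(overrides, `[[`, integer(1), "frame_index")
  contours <- vector("list", n)
  resolved <- logical(n)
  branched <- vapply(skeletons, function(s) s$is_branched, logical(1))
  dtw_scores <- rep(NA_real_, n)
  template <- NULL
  prev_start <- NULL
  for (k in seq_len(n)) {
    sk <- skeletons[[k]]
    eps <- sk$endpoints
    if (nrow(eps) == 0) {
      warning(sprintf("frame %d: skeleton has no endpoints; skipped", k))
      next
    }
    if (is.null(prev_start)) {
      start <- if (is.null(start_rc)) eps[1, ] else {
        d <- (eps[, 1] - start_rc[1])^2 + (eps[, 2] - start_rc[2])^2
        eps[which.min(d), ]
      }
    } else {
      d <- (eps[, 1] - prev_start[1])^2 + (eps[, 2] - prev_start[2])^2
      start <- eps[which.min(d), ]
    }
    has_override <- k %in% ov_frames
    if (k == 1 && sk$is_branched && !has_override) {
      stop(sprintf(
        "frame %d is branched and no template exists; supply a manual override for it",
        k
      ))
    }
    ct <- tryCatch({
      if (has_override && sk$is_branched) {
        ov <- overrides[[match(k, ov_frames)]]
        graph <- build_filament_graph(sk, start = start)
        path_to_contour(graph, path_from_vertex_sequence(graph, ov$region_sequence))
      } else {
        resolve_frame(sk, template = template, start = start, cap = cap)
      }
    }, knottrack_unresolvable = function(e) {
      warning(sprintf("frame %d unresolvable: %s", k, conditionMessage(e)))
      NULL
    })
    if (!is.null(ct)) {
      contours[[k]] <- ct
      resolved[k] <- TRUE
      dtw_scores[k] <- if (!is.null(attr(ct, "dtw"))) attr(ct, "dtw") else NA_real_
      if (template_mode == "resolved" || !sk$is_branched) {
        template <- ct
      }
      prev_start <- ct[1, ]
    }
  }
  structure(list(
    contours = contours, resolved = resolved, branched = branched,
    dtw_scores = dtw_scores, n_frames = n
  ), class = "filament_track")
}

#' @export
print.filament_track <- function(x, ...) {
  cat(sprintf(
    "<filament_track> %d frames: %d resolved (%d branched), %d skipped\n",
    x$n_frames, sum(x$resolved), sum(x$branched & x$resolved),
    sum(!x$resolved)
  ))
  invisible(x)
}
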