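# DTW scoring, path enumeration, contour reconstruction, frame resolution,
# and the tracking loop.

test_that("DTW score satisfies its base cases and identities", {
  a <- cbind(1:5, rep(0, 5))
  expect_equal(dtw_score(a, a), 0)
  expect_equal(dtw_score(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  # symmetric local cost => symmetric score for equal-length contours
  set.seed(31)
  x <- matrix(rnorm(12), 6); y <- matrix(rnorm(12), 6)
  expect_equal(dtw_score(x, y), dtw_score(y, x))
})

test_that("DTW equals the exhaustive monotone-alignment minimum on small contours", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    a <- matrix(runif(2 * n, 0, 10), n)
    b <- matrix(runif(2 * m, 0, 10), m)
    expect_equal(dtw_score(a, b), brute_dtw(a, b), tolerance = 1e-10)
  }
})

test_that("path enumeration handles chains, loops and caps", {
  fix <- make_alpha_fixture()
  start <- fix$skel$endpoints[1, ]
  g <- build_filament_graph(fix$skel, start = start)
  paths <- enumerate_paths(g, cap = 10)
  expect_gt(length(paths), 0)
  # all paths start at the start vertex and end at the end vertex
  for (p in paths) {
    expect_equal(p$vertices[1], g$start_vertex)
    expect_equal(p$vertices[length(p$vertices)], g$end_vertex)
    # no Vf revisited
    kinds <- vapply(g$vertices[p$vertices], `[[`, character(1), "kind")
    vf <- p$vertices[kinds == "Vf"]
    expect_equal(anyDuplicated(vf), 0)
  }
  # among paths covering every segment there are exactly two distinct
  # contours: the two loop orientations
  full <- Filter(function(p) {
    kinds <- vapply(g$vertices[p$vertices], `[[`, character(1), "kind")
    length(unique(p$vertices[kinds == "Vf"])) == g$n_vf
  }, paths)
  expect_gte(length(full), 2)
  contours <- unique(lapply(full, function(p) {
    unname(unclass(path_to_contour(g, p)))
  }))
  expect_equal(length(contours), 2)
  # same pixel set, different sequence
  key <- function(m) sort(m[, 1] * 10000 + m[, 2])
  expect_equal(key(contours[[1]]), key(contours[[2]]))
  expect_false(identical(contours[[1]], contours[[2]]))
})

# Hand-built ladder graph: `k` branch vertices, each offering a choice of
# two alternative segments that reconverge, so 2^k true paths exist.
make_choice_graph <- function(k = 4) {
  vertices <- list(); edges <- NULL
  vid <- 0
  add_v <- function(kind, px) {
    vid <<- vid + 1
    vertices[[vid]] <<- list(id = vid, kind = kind, pixels = matrix(px, 1))
    vid
  }
  start <- add_v("Vf", c(1, 1))
  prev <- start
  for (i in seq_len(k)) {
    b1 <- add_v("Vb", c(i * 10, 1))
    alt_a <- add_v("Vf", c(i * 10, 5))
    alt_b <- add_v("Vf", c(i * 10, -5))
    b2 <- add_v("Vb", c(i * 10 + 5, 1))
    nxt <- add_v("Vf", c(i * 10 + 7, 1))
    edges <- rbind(edges,
      data.frame(vf = prev, vb = b1, attach_row = i * 10, attach_col = 1),
      data.frame(vf = alt_a, vb = b1, attach_row = i * 10, attach_col = 5),
      data.frame(vf = alt_b, vb = b1, attach_row = i * 10, attach_col = -5),
      data.frame(vf = alt_a, vb = b2, attach_row = i * 10, attach_col = 5),
      data.frame(vf = alt_b, vb = b2, attach_row = i * 10, attach_col = -5),
      data.frame(vf = nxt, vb = b2, attach_row = i * 10 + 7, attach_col = 1))
    prev <- nxt
  }
  structure(list(
    vertices = vertices, edges = edges, start_vertex = start,
    end_vertex = prev, start = c(1, 1), shape = c(200, 20),
    n_vf = sum(vapply(vertices, function(v) v$kind == "Vf", logical(1))),
    n_vb = sum(vapply(vertices, function(v) v$kind == "Vb", logical(1)))
  ), class = "filament_graph")
}

test_that("the per-expansion cap bounds combinatorial growth", {
  g <- make_choice_graph(4)   # 2^4 direct routes, more via junction revisits
  paths10 <- enumerate_paths(g, cap = 10, max_paths = 100)
  expect_lte(length(paths10), 100)
  # every returned path is admissible
  kind <- vapply(g$vertices, `[[`, character(1), "kind")
  for (p in paths10) {
    expect_equal(p$vertices[1], g$start_vertex)
    expect_equal(p$vertices[length(p$vertices)], g$end_vertex)
    vf <- p$vertices[kind[p$vertices] == "Vf"]
    expect_equal(anyDuplicated(vf), 0)
  }
  # narrowing the beam can only shrink the result set
  paths2 <- enumerate_paths(g, cap = 2, max_paths = 100)
  expect_lte(length(paths2), length(paths10))
  expect_gte(length(paths2), 1)
  limited <- enumerate_paths(g, cap = 10, max_paths = 5)
  expect_lte(length(limited), 5)
  # a plain chain admits exactly one path
  chain <- make_choice_graph(0)
  expect_length(enumerate_paths(chain), 1)
})

test_that("an unresolvable graph raises the dedicated error", {
  g <- make_choice_graph(1)
  # sever the end vertex: remove all edges touching it
  g$edges <- g$edges[g$edges$vf != g$end_vertex, ]
  expect_error(enumerate_paths(g), class = "knottrack_unresolvable")
})

test_that("key vertex selection ranks by template proximity", {
  fix <- make_alpha_fixture()
  g <- build_filament_graph(fix$skel, start = fix$skel$endpoints[1, ])
  # template = the skeleton itself: every score ~ 0, three ids returned
  tpl <- pixel_contour(fix$skel$pixels)
  key <- select_key_vertices(g, tpl)
  expect_length(key, 3)
  # template far from everything except one vertex: that vertex ranks first
  v1 <- g$vertices[[1]]$pixels
  key2 <- select_key_vertices(g, pixel_contour(v1))
  expect_equal(key2[1], 1)
})

test_that("single-segment paths reduce to geodesic ordering", {
  line <- matrix(FALSE, 5, 12); line[3, 2:11] <- TRUE
  sk <- skeleton(line)
  ct <- resolve_frame(sk, start = c(3, 2))
  expect_equal(unclass(ct), unclass(order_unbranched(sk, c(3, 2))))
})

test_that("resolving a knotted frame against an unknotted template recovers the true contour", {
  sr <- make_knotted_series(n_frames = 20, amplitude_rad = 3.5)
  branched <- vapply(sr$skeletons, function(s) s$is_branched, logical(1))
  t_un <- which(!branched & c(branched[-1], FALSE))[1]  # unbranched frame before a knot
  t_kn <- t_un + 1
  base <- sr$curves[[1]]$points[1, ]
  sk_un <- sr$skeletons[[t_un]]
  d <- (sk_un$endpoints[, 1] - base[2])^2 + (sk_un$endpoints[, 2] - base[1])^2
  tpl <- order_unbranched(sk_un, sk_un$endpoints[which.min(d), ])
  sk_kn <- sr$skeletons[[t_kn]]
  d2 <- (sk_kn$endpoints[, 1] - base[2])^2 + (sk_kn$endpoints[, 2] - base[1])^2
  ct <- resolve_frame(sk_kn, template = tpl,
                      start = sk_kn$endpoints[which.min(d2), ])
  expect_lte(frechet_distance(unclass(ct), truth_rc(sr$curves[[t_kn]])), 2)
  # no invented pixels: resolved contour is a subset of the skeleton
  in_skel <- sk_kn$mask[unclass(ct)]
  expect_true(all(in_skel))
  # robustness: rigidly shifting the template by up to 2 px does not change
  # the selected path
  tpl_shift <- pixel_contour(unclass(tpl) + 1L)
  ct_shift <- resolve_frame(sk_kn, template = tpl_shift,
                            start = sk_kn$endpoints[which.min(d2), ])
  expect_equal(unclass(ct_shift), unclass(ct), ignore_attr = TRUE)
})

test_that("tracking an all-unbranched series equals independent geodesic ordering", {
  sr <- make_knotted_series(n_frames = 6, amplitude_rad = 1.0)
  base <- sr$curves[[1]]$points[1, ]
  tr <- track_series(sr$skeletons, start_rc = c(base[2], base[1]))
  expect_true(all(tr$resolved))
  for (k in seq_along(sr$skeletons)) {
    sk <- sr$skeletons[[k]]
    d <- (sk$endpoints[, 1] - base[2])^2 + (sk$endpoints[, 2] - base[1])^2
    ind <- order_unbranched(sk, sk$endpoints[which.min(d), ])
    expect_equal(unclass(tr$contours[[k]]), unclass(ind))
  }
})

test_that("a manual override is followed verbatim and frame-1 knots need one", {
  fix <- make_alpha_fixture()
  sk <- fix$skel
  expect_error(track_series(list(sk)), "manual override")

  start <- sk$endpoints[1, ]
  g <- build_filament_graph(sk, start = start)
  # deliberately choose the loop-skipping path
  skip_seq <- c(g$start_vertex, g$n_vf + 1, g$end_vertex)
  ov <- manual_override(1, skip_seq)
  tr <- track_series(list(sk), start_rc = start, overrides = list(ov))
  expect_true(tr$resolved[1])
  want <- path_to_contour(
    g, knottrack:::path_from_vertex_sequence(g, skip_seq))
  expect_equal(unclass(tr$contours[[1]]), unclass(want))
})

test_that("tracking a knotted beating series stays close to ground truth", {
  sr <- make_knotted_series(n_frames = 20, amplitude_rad = 3.5)
  branched <- vapply(sr$skeletons, function(s) s$is_branched, logical(1))
  f0 <- which(!branched)[1]
  base <- sr$curves[[1]]$points[1, ]
  tr <- track_series(sr$skeletons[f0:20], start_rc = c(base[2], base[1]))
  expect_true(all(tr$resolved))
  bench <- benchmark_track(tr, sr$curves[f0:20])
  expect_lt(mean(bench$mean_err_px), 1)
  expect_gt(mean(bench$dice), 0.9)
  expect_lt(stats::median(bench$frechet_px), 3)
})
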