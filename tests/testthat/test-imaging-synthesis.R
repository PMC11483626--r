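# Traveling-wave generator, rasterization, image formation, noise model.

test_that("zero-amplitude generator yields identical straight frames clamped at the base", {
  p <- wave_params(length_um = 10, pixel_size_um = 0.1, amplitude_rad = 0,
                   bias_rad = 0, n_frames = 5)
  curves <- generate_beating_filament(p)
  L <- 10 / 0.1
  for (cv in curves) {
    expect_equal(curve_arc_length(cv), L, tolerance = 1e-6)
    expect_equal(end_to_end_distance(cv$points), L, tolerance = 1e-6)
    expect_equal(cv$points, curves[[1]]$points)
  }
})

test_that("the clamped base point and arc length are conserved across frames", {
  p <- wave_params(length_um = 20, pixel_size_um = 0.1, amplitude_rad = 3.5,
                   wavelength_um = 15, n_frames = 12)
  curves <- generate_beating_filament(p)
  L <- 20 / 0.1
  base <- curves[[1]]$points[1, ]
  for (cv in curves) {
    expect_equal(cv$points[1, ], base)
    expect_lt(abs(curve_arc_length(cv) - L) / L, 0.01)
  }
})

test_that("high-amplitude beating produces self-intersecting (knotted) frames", {
  sr <- make_knotted_series(n_frames = 20, amplitude_rad = 3.5)
  branched <- vapply(sr$skeletons, function(s) s$is_branched, logical(1))
  expect_gt(sum(branched), 0)
  # low amplitude never knots
  lo <- make_knotted_series(n_frames = 10, amplitude_rad = 0.5)
  expect_false(any(vapply(lo$skeletons, function(s) s$is_branched, logical(1))))
})

test_that("invalid wave parameters are rejected", {
  expect_error(wave_params(length_um = -1), "length_um")
  expect_error(wave_params(n_frames = 0), "n_frames")
  expect_error(wave_params(amplitude_rad = NaN), "finite")
  p <- wave_params(length_um = 20, pixel_size_um = 0.1,
                   base_xy = c(5, 5), n_frames = 1)
  expect_error(generate_beating_filament(p, shape = c(40, 40)), "canvas")
})

test_that("rasterization covers the curve at sub-pixel distance", {
  # axis-aligned segment: one lit pixel per column in the segment's row
  seg <- cbind(x = seq(1, 11, by = 0.25), y = rep(6, 41))
  mask <- rasterize_skeleton(filament_curve(seg), c(12, 15))
  expect_equal(sum(mask), 11)
  expect_true(all(which(mask, arr.ind = TRUE)[, 1] == 6))

  # single point
  m1 <- rasterize_skeleton(matrix(c(4, 7), 1), c(10, 10))
  expect_equal(sum(m1), 1)
  expect_true(m1[7, 4])

  # sine arc: every lit pixel within 0.71 px of the continuous curve and
  # every curve point within sqrt(2) of a lit pixel
  t <- seq(0, 2 * pi, length.out = 2000)
  pts <- cbind(x = 10 + 30 * t / (2 * pi), y = 20 + 8 * sin(t))
  mask <- rasterize_skeleton(filament_curve(pts), c(40, 50))
  lit <- which(mask, arr.ind = TRUE)
  lit_xy <- cbind(lit[, 2], lit[, 1])
  d_lit <- vapply(seq_len(nrow(lit_xy)), function(i) {
    min(sqrt((pts[, 1] - lit_xy[i, 1])^2 + (pts[, 2] - lit_xy[i, 2])^2))
  }, numeric(1))
  expect_lte(max(d_lit), 0.71)
  d_curve <- vapply(seq_len(nrow(pts)), function(i) {
    min(sqrt((lit_xy[, 1] - pts[i, 1])^2 + (lit_xy[, 2] - pts[i, 2])^2))
  }, numeric(1))
  expect_lte(max(d_curve), sqrt(2))
})

test_that("rendering uses a 13-pixel diamond dilation and a unit-sum PSF kernel", {
  single <- matrix(FALSE, 11, 11); single[6, 6] <- TRUE
  dil <- knottrack:::dilate_plus(knottrack:::dilate_plus(single))
  expect_equal(sum(dil), 13)
  idx <- which(dil, arr.ind = TRUE)
  expect_true(all(abs(idx[, 1] - 6) + abs(idx[, 2] - 6) <= 2))

  expect_equal(sum(knottrack:::gaussian_kernel_3x3(2)), 1)

  img <- render_image(single)
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(max(img), 1)
  # symmetric input -> symmetric image
  expect_equal(img, img[11:1, ])
  expect_equal(img, t(img))

  empty <- render_image(matrix(FALSE, 5, 5))
  expect_true(all(empty == 0))
})

test_that("SNR conversion follows the decibel law", {
  expect_equal(snr_db_to_linear(10), 10)
  expect_equal(snr_db_to_linear(20), 100)
  expect_equal(snr_db_to_linear(0), 1)
})

test_that("Gaussian noise has power P_signal / SNR_linear", {
  set.seed(11)
  img <- matrix(runif(512 * 512), 512)
  p_signal <- var(as.vector(img))
  snr_db <- 10
  noisy <- add_gaussian_noise(img, snr_db, seed = 5)
  p_noise_expected <- p_signal / 10
  expect_lt(abs(var(as.vector(noisy - img)) - p_noise_expected) /
              p_noise_expected, 0.05)
  # hand-evaluated: variance 0.04 at 10 dB -> sigma = sqrt(0.004)
  img2 <- matrix(rnorm(10000, sd = 0.2), 100)
  img2 <- (img2 - mean(img2)) * (0.2 / sd(img2))
  expect_equal(var(as.vector(img2)), 0.04, tolerance = 1e-12)
  noisy2 <- add_gaussian_noise(img2, 10, seed = 6)
  expect_equal(sd(as.vector(noisy2 - img2)), sqrt(0.004), tolerance = 0.05)
  # vanishing noise power at very high SNR
  expect_equal(add_gaussian_noise(img, 300, seed = 7), img, tolerance = 1e-6)
  # zero-variance image returned unchanged
  flat <- matrix(0.5, 10, 10)
  expect_identical(add_gaussian_noise(flat, 10, seed = 8), flat)
})

test_that("salt-and-pepper noise corrupts the requested pixel fraction", {
  img <- matrix(0.5, 100, 100)
  expect_identical(add_salt_pepper_noise(img, 0, seed = 1), img)
  all01 <- add_salt_pepper_noise(img, 1, seed = 2)
  expect_true(all(all01 %in% c(0, 1)))
  corrupted <- add_salt_pepper_noise(img, 0.1, seed = 3)
  n_hit <- sum(corrupted != img)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(n_hit, ci[1])
  expect_lte(n_hit, ci[2])
})

test_that("frame synthesis is reproducible for a fixed seed and hits the requested SNR", {
  p <- wave_params(length_um = 10, pixel_size_um = 0.1, amplitude_rad = 2,
                   n_frames = 10)
  a <- synthesize_series(p, snr_db = 10, seed = 99)
  b <- synthesize_series(p, snr_db = 10, seed = 99)
  expect_identical(a, b)
  # empirical SNR within 0.5 dB over the 10 frames
  clean <- synthesize_series(p, snr_db = NULL)
  snr_emp <- vapply(seq_along(a), function(k) {
    noise <- a[[k]]$image - clean[[k]]$image
    10 * log10(var(as.vector(clean[[k]]$image)) / var(as.vector(noise)))
  }, numeric(1))
  expect_lt(max(abs(snr_emp - 10)), 0.5)
})

test_that("rasterized non-intersecting curves contain no branch pixels", {
  sr <- make_knotted_series(n_frames = 8, amplitude_rad = 1.0)
  for (s in sr$skeletons) {
    expect_equal(nrow(find_branch_pixels(s)), 0)
  }
})

test_that("synthetic stacks round-trip through TIFF plus truth CSV", {
  p <- wave_params(length_um = 8, pixel_size_um = 0.1, amplitude_rad = 1,
                   n_frames = 3)
  frames <- synthesize_series(p, snr_db = 20, seed = 4)
  tif <- tempfile(fileext = ".tif"); csvf <- tempfile(fileext = ".csv")
  write_synthetic_stack(frames, tif, csvf)
  imgs <- read_image_stack(tif)
  expect_length(imgs, 3)
  expect_equal(dim(imgs[[1]]), dim(frames[[1]]$image))
  truth <- read.csv(csvf)
  expect_equal(sort(unique(truth$frame)), 1:3)
  # 0-based export of 1-based internal coordinates
  expect_equal(truth$x[truth$frame == 1][1],
               unname(frames[[1]]$truth_curve$points[1, 1] - 1))
})
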