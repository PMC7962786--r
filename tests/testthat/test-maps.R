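geom <- small_geom()
frame <- small_frame(geom)
kern <- kernel_spec()          # 1.5 deg = 15 px at this scale
sigma_px <- 1.5 * px_per_degree(geom)
cx <- frame$origin_x_px + frame$width_px / 2
cy <- frame$origin_y_px + frame$height_px / 2

test_that("single-kernel map peaks at the fixation and is symmetric", {
  m <- build_fixation_map(cx, cy, kernel = kern, frame = frame, geom = geom)
  idx <- which(m$grid == max(m$grid), arr.ind = TRUE)
  expect_equal(as.numeric(idx[1, "col"]) - 1, cx - frame$origin_x_px)
  expect_equal(as.numeric(idx[1, "row"]) - 1, cy - frame$origin_y_px)
  # radial symmetry up to grid quantization
  v1 <- map_value_at(m, cx + 10, cy)
  expect_equal(v1, map_value_at(m, cx - 10, cy), tolerance = 1e-12)
  expect_equal(v1, map_value_at(m, cx, cy + 10), tolerance = 1e-12)
})

test_that("maps are linear in repeated points and conserve mass", {
  m1 <- build_fixation_map(cx, cy, kernel = kern, frame = frame, geom = geom)
  m3 <- build_fixation_map(rep(cx, 3), rep(cy, 3), kernel = kern,
                           frame = frame, geom = geom)
  expect_equal(m3$grid, 3 * m1$grid, tolerance = 1e-12)

  # two points 10 sigma apart: equal local maxima, mass = 2 x single
  # kernel; needs a frame wide enough that neither kernel is edge-clipped
  wide <- image_frame(380, 160, geom = geom)
  wcx <- wide$origin_x_px + wide$width_px / 2
  wcy <- wide$origin_y_px + wide$height_px / 2
  x2 <- c(wcx - 5 * sigma_px, wcx + 5 * sigma_px)
  m2 <- build_fixation_map(x2, c(wcy, wcy), kernel = kern, frame = wide,
                           geom = geom)
  mw1 <- build_fixation_map(wcx, wcy, kernel = kern, frame = wide,
                            geom = geom)
  oracle <- dense_gaussian_sum(x2, c(wcy, wcy), c(1, 1), sigma_px, wide) /
    (2 * pi * sigma_px^2)
  # the map truncates each kernel on a +-4 sigma square window, losing
  # about 1.3e-4 of its mass relative to the untruncated oracle
  expect_equal(sum(m2$grid), sum(oracle), tolerance = 5e-4)
  expect_equal(sum(m2$grid), 2 * sum(mw1$grid), tolerance = 1e-6)
  expect_equal(map_value_at(m2, x2[1], wcy), map_value_at(m2, x2[2], wcy),
               tolerance = 1e-9)
})

test_that("normalizations meet their stated tolerances", {
  set.seed(9)
  m <- build_fixation_map(stats::runif(8, cx - 80, cx + 80),
                          stats::runif(8, cy - 50, cy + 50),
                          kernel = kern, frame = frame, geom = geom)
  z <- normalize_map(m, "zscore")
  expect_lt(abs(mean(z$grid)), 1e-9)
  expect_lt(abs(mean(z$grid^2) - 1), 1e-6)
  mx <- normalize_map(m, "max1")
  expect_identical(max(mx$grid), 1)
  ms <- normalize_map(m, "mass1")
  expect_equal(sum(ms$grid), 1, tolerance = 1e-12)
})

test_that("NSS sign contract: congruent > 0, incoherent < 0", {
  # observers 1..4 share one location; the left-out observer fixates it too
  shared <- data.frame(observer = rep(1:5, each = 2),
                       x_px = cx + rep(c(-3, 3), 5), y_px = cy)
  r <- nss_loo(shared, kern, frame, geom)
  expect_true(all(r$defined))
  expect_true(all(r$nss > 0))

  # left-out fixations at the far corner (minimum of the others' map)
  inco <- shared
  inco$x_px[inco$observer == 5] <- frame$origin_x_px + 5
  inco$y_px[inco$observer == 5] <- frame$origin_y_px + 5
  r <- nss_loo(inco, kern, frame, geom)
  expect_lt(r$nss[r$observer == 5], 0)
})

test_that("NSS is invariant to rigid translation of all fixations", {
  # exact invariance requires no kernel to be edge-clipped before or after
  # the shift, so positions stay > 4 sigma + shift away from frame edges
  set.seed(4)
  d <- data.frame(observer = rep(1:4, each = 3),
                  x_px = stats::runif(12, cx - 40, cx + 40),
                  y_px = stats::runif(12, cy - 10, cy + 10))
  r1 <- nss_loo(d, kern, frame, geom)
  d2 <- d
  d2$x_px <- d2$x_px + 15
  d2$y_px <- d2$y_px - 5
  r2 <- nss_loo(d2, kern, frame, geom)
  expect_equal(r1$nss, r2$nss, tolerance = 1e-6)
})

test_that("sum aggregation equals mean x fixation count", {
  set.seed(5)
  d <- data.frame(observer = rep(1:3, each = 4),
                  x_px = stats::runif(12, cx - 40, cx + 40),
                  y_px = stats::runif(12, cy - 30, cy + 30))
  rm_ <- nss_loo(d, kern, frame, geom, aggregate = "mean")
  rs <- nss_loo(d, kern, frame, geom, aggregate = "sum")
  expect_equal(rs$nss, rm_$nss * rm_$n_fixations_used, tolerance = 1e-9)
})

test_that("dispersion behaves like a spatial spread measure", {
  # coincident points equal the single-fixation baseline
  base <- dispersion(cx, cy, kern, frame, geom)
  expect_equal(dispersion(rep(cx, 4), rep(cy, 4), kern, frame, geom), base,
               tolerance = 1e-12)
  expect_gt(base, 0)
  expect_lte(base, 1)

  # non-decreasing in separation over the widest in-frame range (7 sigma;
  # beyond that the kernels would be edge-clipped on this image); even-pixel
  # separations keep both peaks on grid points, avoiding quantization noise
  seps <- 2 * round(seq(0, 3.5 * sigma_px, length.out = 8))
  scores <- vapply(seps, function(s) {
    dispersion(c(cx - s / 2, cx + s / 2), c(cy, cy), kern, frame, geom)
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))

  # a fine lattice tiling the image approaches the maximum for that n
  gx <- seq(frame$origin_x_px + 8, frame$origin_x_px + frame$width_px - 8,
            length.out = 8)
  gy <- seq(frame$origin_y_px + 8, frame$origin_y_px + frame$height_px - 8,
            length.out = 5)
  lat <- expand.grid(x = gx, y = gy)
  expect_gt(dispersion(lat$x, lat$y, kern, frame, geom), 10 * base)

  # shrinking toward the centroid never increases the score
  set.seed(6)
  x <- stats::runif(10, cx - 80, cx + 80)
  y <- stats::runif(10, cy - 50, cy + 50)
  full <- dispersion(x, y, kern, frame, geom)
  for (sh in c(0.7, 0.4, 0.1)) {
    sc <- dispersion(mean(x) + sh * (x - mean(x)),
                     mean(y) + sh * (y - mean(y)), kern, frame, geom)
    expect_lte(sc, full + 1e-12)
    full <- sc
  }
})

test_that("group heatmaps are duration-weighted unit-mass densities", {
  m1 <- group_heatmap(cx, cy, 300, kern, frame, geom)
  expect_equal(sum(m1$grid), 1, tolerance = 1e-12)
  k <- normalize_map(build_fixation_map(cx, cy, kernel = kern, frame = frame,
                                        geom = geom), "mass1")
  expect_equal(m1$grid, k$grid, tolerance = 1e-12)

  # doubling all durations changes nothing
  x <- c(cx - 40, cx + 40, cx)
  y <- c(cy, cy, cy - 30)
  w <- c(200, 300, 500)
  expect_equal(group_heatmap(x, y, w, kern, frame, geom)$grid,
               group_heatmap(x, y, 2 * w, kern, frame, geom)$grid,
               tolerance = 1e-12)

  # disjoint clusters of equal total duration carry equal mass; placement
  # symmetric about the grid centre (pixel index (w-1)/2) so any edge
  # clipping is identical on both sides
  mid <- frame$origin_x_px + (frame$width_px - 1) / 2
  m <- group_heatmap(c(mid - 70, mid + 70), c(cy, cy), c(400, 400), kern,
                     frame, geom)
  left <- sum(m$grid[, seq_len(ncol(m$grid) / 2)])
  expect_equal(left, 0.5, tolerance = 1e-6)
})

test_that("difference maps are signed, zero-sum and antisymmetric", {
  a <- group_heatmap(cx - 30, cy, 300, kern, frame, geom)
  b <- group_heatmap(cx + 30, cy, 300, kern, frame, geom)
  d <- difference_map(a, b)
  expect_lt(abs(sum(d$grid)), 1e-9)
  d2 <- difference_map(b, a)
  expect_equal(d$grid, -d2$grid, tolerance = 1e-12)
  expect_equal(difference_map(a, a)$grid, 0 * a$grid)

  small <- group_heatmap(cx, cy, 300, kern,
                         image_frame(100, 80, geom = geom), geom)
  expect_error(difference_map(a, small), "shape")
  expect_error(difference_map(a, normalize_map(b, "max1")), "mass1")
})

test_that("maps round-trip through the portable text format", {
  m <- group_heatmap(c(cx, cx + 20), c(cy, cy), c(100, 200), kern, frame,
                     geom, grid_step = 4L)
  p <- withr::local_tempfile(fileext = ".txt")
  write_map(m, p)
  m2 <- read_map(p)
  expect_equal(m2$grid, m$grid, tolerance = 1e-12)
  expect_equal(m2$normalization, "mass1")
  expect_equal(m2$grid_step, 4)
})
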