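test_that("pixel-centre rasterisation matches exhaustive counting on squares", {
  g <- grid_geometry(c(-2, -2, 0), c(1, 1, 1), c(15, 15, 1))
  # [0,10) x [0,10) on a 1 mm grid: exactly the 100 centres 0..9
  m <- rasterize(rt_structure("S", list(square_contour(0, 0, 10, 0))), g)
  expect_equal(sum(m$voxels), 100L)

  # exhaustive oracle: centre-in-polygon by direct point evaluation
  centres <- expand.grid(x = grid_axis(g, 1), y = grid_axis(g, 2))
  expect_equal(sum(centres$x >= 0 & centres$x < 10 &
                   centres$y >= 0 & centres$y < 10), 100L)
})

test_that("even-odd rule carves holes from nested coplanar contours", {
  g <- grid_geometry(c(-2, -2, 0), c(1, 1, 1), c(15, 15, 1))
  s <- rt_structure("ring", list(square_contour(0, 0, 10, 0),
                                 square_contour(3, 3, 4, 0)))
  m <- rasterize(s, g)
  expect_equal(sum(m$voxels), 100L - 16L)
  # XOR behaviour, exhaustively: inner voxels off, annulus on
  inner <- m$voxels[grid_axis(g, 1) %in% 3:6, grid_axis(g, 2) %in% 3:6, 1]
  expect_false(any(inner))
})

test_that("empty structure rasterises to an all-false mask with zero volume", {
  g <- tiny_geometry(c(5, 5, 5))
  m <- rasterize(rt_structure("empty"), g)
  expect_false(any(m$voxels))
  expect_equal(mask_volume(m), 0)
})

test_that("rasterised ellipsoid volume is within 1% of 4/3 pi abc", {
  semi <- c(30, 25, 20)
  g <- grid_geometry(c(-35, -30, -25), c(1, 1, 1), c(71, 61, 51))
  cts <- sabrcheck:::.ellipsoid_contours(c(0, 0, 0), semi, grid_axis(g, 3), 128)
  m <- rasterize(rt_structure("E", cts), g)
  analytic <- 4 / 3 * pi * prod(semi) / 1000
  expect_lt(abs(mask_volume(m) - analytic) / analytic, 0.01)
})

test_that("rasterisation error shrinks as the grid is refined", {
  semi <- c(18, 15, 12)
  analytic <- 4 / 3 * pi * prod(semi) / 1000
  err <- vapply(c(2, 1, 0.5), function(sp) {
    n <- as.integer(2 * ceiling(22 / sp) + 1)
    g <- grid_geometry(-ceiling(22 / sp) * sp * c(1, 1, 1), rep(sp, 3),
                       c(n, n, n))
    cts <- sabrcheck:::.ellipsoid_contours(c(0, 0, 0), semi,
                                           grid_axis(g, 3), 192)
    abs(mask_volume(rasterize(rt_structure("E", cts), g)) - analytic)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("rasterisation is equivariant under integer-voxel translation", {
  g <- grid_geometry(c(-20, -20, -5), c(1, 1, 1), c(41, 41, 11))
  cts <- sabrcheck:::.ellipsoid_contours(c(0.3, -0.2, 0.1), c(9, 7, 4),
                                         grid_axis(g, 3), 64)
  m1 <- rasterize(rt_structure("E", cts), g)
  shifted <- lapply(cts, function(ct)
    rt_contour(sweep(ct$points, 2, c(3, -2, 1), `+`)))
  m2 <- rasterize(rt_structure("E", shifted), g)
  # translate mask m1 by (3, -2, 1) voxels and compare interior
  expect_equal(m2$voxels[9:35, 4:30, 3:10], m1$voxels[6:32, 6:32, 2:9])
})

test_that("contours far from any grid slice are an error", {
  g <- tiny_geometry(c(5, 5, 3))
  ct <- square_contour(0, 0, 3, 7.2)  # grid slices at z = 0, 1, 2
  expect_error(rasterize(rt_structure("S", list(ct)), g), "7.2")
})

test_that("mask volume is count times voxel volume", {
  g <- tiny_geometry(c(3, 3, 3))
  v <- array(FALSE, c(3, 3, 3)); v[2, 2, 2] <- TRUE
  expect_equal(mask_volume(binary_mask(v, g)), 0.001)
  g2 <- grid_geometry(c(0, 0, 0), c(2, 1.5, 1), c(3, 3, 3))
  expect_equal(mask_volume(binary_mask(v, g2)), 0.003)
})

test_that("expansion of a single voxel approximates a Euclidean ball", {
  g <- tiny_geometry(c(15, 15, 15))
  v <- array(FALSE, c(15, 15, 15)); v[8, 8, 8] <- TRUE
  m5 <- expand_mask(binary_mask(v, g), 5)
  analytic <- 4 / 3 * pi * 5^3 / 1000
  expect_lt(abs(mask_volume(m5) - analytic) / analytic, 0.10)
})

test_that("expansion identity, monotonicity, and error contracts", {
  g <- tiny_geometry(c(12, 12, 12))
  set.seed(3)
  v <- array(runif(12^3) < 0.1, c(12, 12, 12))
  m <- binary_mask(v, g)
  expect_identical(expand_mask(m, 0)$voxels, m$voxels)
  m2 <- expand_mask(m, 2)
  m3 <- expand_mask(m, 3.5)
  expect_true(all(m$voxels <= m2$voxels))
  expect_true(all(m2$voxels <= m3$voxels))
  expect_error(expand_mask(m, -1), "non-negative")
})

test_that("expansion agrees with brute-force Euclidean dilation", {
  g <- tiny_geometry(c(9, 9, 9))
  set.seed(8)
  v <- array(runif(9^3) < 0.08, c(9, 9, 9))
  m <- expand_mask(binary_mask(v, g), 2.5)
  # oracle: distance from every voxel centre to every set voxel centre
  idx <- which(v); ai <- arrayInd(idx, c(9, 9, 9))
  all_ai <- arrayInd(seq_len(9^3), c(9, 9, 9))
  d2 <- outer(rowSums(all_ai^2), rowSums(ai^2), `+`) -
    2 * all_ai %*% t(ai)
  oracle <- apply(d2, 1, min) <= 2.5^2 + 1e-9
  expect_equal(as.vector(m$voxels), oracle)
})

test_that("2-D expansion never crosses slices", {
  g <- tiny_geometry(c(11, 11, 5))
  v <- array(FALSE, c(11, 11, 5)); v[6, 6, 3] <- TRUE
  m <- expand_mask(binary_mask(v, g), 3, mode = "2d")
  expect_true(all(!m$voxels[, , c(1, 2, 4, 5)]))
  expect_equal(sum(m$voxels[, , 3]), sum(outer((-5:5)^2, (-5:5)^2, `+`) <= 9 + 1e-9))
})

test_that("volume comparison arithmetic and the under-filled flag", {
  v <- compare_volumes(300, 150)
  expect_equal(v$delta_v, -150)
  expect_equal(v$ratio_pct, 50)
  expect_equal(v$deviation_pct, -50)
  expect_true(v$under_filled)

  v2 <- compare_volumes(300, 300)
  expect_equal(v2$delta_v, 0)
  expect_equal(v2$ratio_pct, 100)
  expect_false(v2$under_filled)

  # a severely under-filled bladder: 577 cm^3 planned, 136.2 cm^3 daily
  v3 <- compare_volumes(577, 136.2)
  expect_equal(round(v3$ratio_pct, 1), 23.6)
  expect_true(v3$under_filled)

  # deviation = ratio - 100 exactly, across random inputs
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 10, 500); b <- runif(1, 1, 800)
    vc <- compare_volumes(a, b)
    expect_identical(vc$deviation_pct, vc$ratio_pct - 100)
    expect_equal(sign(vc$delta_v), sign(vc$deviation_pct))
  }
  expect_error(compare_volumes(0, 10), "positive")
})

test_that("anterior distension slice counting", {
  g <- tiny_geometry(c(21, 21, 9))
  mk <- function(ymin, slices) {
    v <- array(FALSE, c(21, 21, 9))
    for (k in slices) v[5:15, (ymin + 1):18, k] <- TRUE
    binary_mask(v, g)
  }
  base <- mk(8, 1:9)
  expect_equal(anterior_distension_slices(base, base), 0L)
  # daily reaches 2 voxels more anterior on exactly 5 slices
  daily <- base
  daily$voxels[5:15, 7:8, 3:7] <- TRUE
  expect_equal(anterior_distension_slices(daily, base), 5L)
  # on exactly 2 slices (below the >= 3 decision trigger)
  daily2 <- base
  daily2$voxels[5:15, 7:8, 4:5] <- TRUE
  expect_equal(anterior_distension_slices(daily2, base), 2L)
  # empty slices are skipped
  part <- mk(8, 1:4)
  expect_equal(anterior_distension_slices(part, base), 0L)
  g2 <- tiny_geometry(c(21, 21, 9), origin = c(1, 0, 0))
  expect_error(anterior_distension_slices(daily, binary_mask(base$voxels, g2)),
               "geometry")
})
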