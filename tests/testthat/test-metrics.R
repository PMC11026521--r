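# Dice, HD95, Bland-Altman, and ICC against hand computations and
# brute-force oracles.

box_vol <- function(shape, lo, hi, spacing = c(1, 1, 1)) {
  a <- array(0L, shape)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  label_volume(a, spacing = spacing)
}

test_that("dice matches exact overlap counts", {
  fix <- make_shifted_box_volumes(c(20, 12, 12), c(10, 10, 10), c(5, 0, 0))
  expect_identical(dice(fix$a, fix$b, 1L), 0.5)
  expect_identical(dice(fix$a, fix$a, 1L), 1)
  far <- make_shifted_box_volumes(c(30, 8, 8), c(6, 6, 6), c(10, 0, 0))
  expect_identical(dice(far$a, far$b, 1L), 0)
  expect_identical(dice(fix$a, fix$b, 1L), dice(fix$b, fix$a, 1L))
})

test_that("dice empty-label conventions: both empty 1 with warning, one empty 0", {
  a <- label_volume(array(0L, c(5, 5, 5)))
  b <- label_volume(array(0L, c(5, 5, 5)))
  expect_warning(val <- dice(a, b, 1L), "absent from both")
  expect_identical(val, 1)
  c1 <- box_vol(c(5, 5, 5), c(2, 2, 2), c(3, 3, 3))
  expect_identical(suppressWarnings(dice(a, c1, 1L)), 0)
})

test_that("mismatched grids are a geometry error", {
  a <- box_vol(c(5, 5, 5), c(1, 1, 1), c(2, 2, 2))
  b <- box_vol(c(6, 5, 5), c(1, 1, 1), c(2, 2, 2))
  expect_error(dice(a, b, 1L), class = "aaa_geometry_error")
  c2 <- box_vol(c(5, 5, 5), c(1, 1, 1), c(2, 2, 2), spacing = c(1, 1, 2))
  expect_error(hd95(a, c2, 1L), class = "aaa_geometry_error")
})

test_that("hd95 on simple configurations matches hand values", {
  a <- box_vol(c(12, 5, 5), c(2, 2, 2), c(2, 2, 2))
  b <- box_vol(c(12, 5, 5), c(5, 2, 2), c(5, 2, 2))
  expect_equal(hd95(a, b, 1L), 3, tolerance = 1e-12)  # single voxel pair
  expect_identical(hd95(a, a, 1L), 0)
  # parallel 1-voxel plates 4 voxels apart: every boundary distance is 4
  p1 <- box_vol(c(10, 6, 6), c(2, 1, 1), c(2, 6, 6))
  p2 <- box_vol(c(10, 6, 6), c(6, 1, 1), c(6, 6, 6))
  expect_equal(hd95(p1, p2, 1L), 4, tolerance = 1e-12)
  # spacing scales physical distances
  a2 <- box_vol(c(12, 5, 5), c(2, 2, 2), c(2, 2, 2), spacing = c(2, 1, 1))
  b2 <- box_vol(c(12, 5, 5), c(5, 2, 2), c(5, 2, 2), spacing = c(2, 1, 1))
  expect_equal(hd95(a2, b2, 1L), 6, tolerance = 1e-12)
  empty <- label_volume(array(0L, c(12, 5, 5)))
  expect_error(hd95(a, empty, 1L), class = "aaa_undefined_distance")
})

test_that("hd95 equals the brute-force all-pairs oracle on random small masks", {
  set.seed(99)
  for (i in 1:8) {
    d <- c(sample(8:14, 1), sample(8:14, 1), sample(8:14, 1))
    sp <- runif(3, 0.5, 2)
    mk <- function() {
      m <- array(runif(prod(d)) < 0.2, d)
      if (!any(m)) m[2, 2, 2] <- TRUE
      m
    }
    ma <- mk(); mb <- mk()
    va <- label_volume(array(as.integer(ma), d), spacing = sp)
    vb <- label_volume(array(as.integer(mb), d), spacing = sp)
    expect_equal(hd95(va, vb, 1L), hd95_oracle(ma, mb, sp), tolerance = 1e-9)
    # symmetric by construction, bounded by the exact Hausdorff distance
    expect_identical(hd95(va, vb, 1L), hd95(vb, va, 1L))
    expect_lte(hd95(va, vb, 1L), hausdorff_max_oracle(ma, mb, sp) + 1e-12)
  }
})

test_that("dice and hd95 are invariant under a common voxel translation", {
  a <- box_vol(c(20, 20, 20), c(3, 3, 3), c(8, 9, 10))
  b <- box_vol(c(20, 20, 20), c(5, 4, 3), c(10, 10, 10))
  shift <- function(v, by) {
    arr <- array(0L, dim(v$voxels))
    arr[(1 + by[1]):20, (1 + by[2]):20, (1 + by[3]):20] <-
      v$voxels[1:(20 - by[1]), 1:(20 - by[2]), 1:(20 - by[3])]
    label_volume(arr, v$spacing)
  }
  a2 <- shift(a, c(4, 2, 1)); b2 <- shift(b, c(4, 2, 1))
  expect_identical(dice(a, b, 1L), dice(a2, b2, 1L))
  expect_equal(hd95(a, b, 1L), hd95(a2, b2, 1L), tolerance = 1e-12)
})

test_that("dice(A,A) = 1 and hd95(A,A) = 0 on random masks", {
  set.seed(5)
  for (i in 1:50) {
    d <- c(7, 8, 9)
    m <- array(runif(prod(d)) < 0.3, d)
    if (!any(m)) m[3, 3, 3] <- TRUE
    v <- label_volume(array(as.integer(m), d))
    expect_identical(dice(v, v, 1L), 1)
    expect_identical(hd95(v, v, 1L), 0)
  }
})

test_that("bland_altman reproduces hand-computed limits of agreement", {
  r <- bland_altman(c(1, 2, 3), c(2, 2, 2))
  expect_identical(r$bias, 0)
  expect_identical(r$sd, 1)
  expect_identical(r$loa_low, -1.96)
  expect_identical(r$loa_high, 1.96)
  expect_identical(r$n_used, 3L)

  same <- bland_altman(c(4, 5, 6), c(4, 5, 6))
  expect_identical(c(same$bias, same$sd, same$loa_low, same$loa_high), c(0, 0, 0, 0))

  off <- bland_altman(c(1, 2, 3), c(3, 4, 5))
  expect_identical(off$bias, -2)
  expect_identical(off$sd, 0)

  expect_error(bland_altman(1:3, 1:4), class = "aaa_input_error")
  expect_error(bland_altman(1, 1), class = "aaa_input_error")
})

test_that("bland_altman bias is antisymmetric and sd swap-invariant", {
  set.seed(21)
  x <- rnorm(40, 50, 8); y <- x + rnorm(40, 1.5, 2)
  f <- bland_altman(x, y); g <- bland_altman(y, x)
  expect_equal(f$bias, -g$bias, tolerance = 1e-12)
  expect_equal(f$sd, g$sd, tolerance = 1e-12)
  expect_equal(f$loa_high - f$bias, 1.96 * f$sd, tolerance = 1e-12)
})

test_that("outlier removal drops points outside the initial limits exactly once", {
  x <- c(rep(10, 20), 40)     # one gross outlier in the differences
  y <- rep(10, 21)
  r <- bland_altman(x, y, remove_outliers = TRUE)
  expect_identical(r$outliers_removed, 1L)
  expect_identical(r$n_used, 20L)
  expect_identical(r$bias, 0)
  expect_identical(r$initial$n_used, 21L)
  expect_gt(r$initial$sd, r$sd)
})

test_that("icc is 1 for identical observer columns and handles zero variance", {
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_identical(icc(m), 1)
  flat <- matrix(5, 4, 3)
  expect_warning(v <- icc(flat), "zero total variance")
  expect_identical(v, 1)
  expect_error(icc(cbind(c(1, NA), c(2, 3))), class = "aaa_input_error")
  expect_error(icc(matrix(1:3, 3, 1)), class = "aaa_input_error")
})

test_that("icc(2,1) matches the two-way ANOVA oracle", {
  base <- c(1, 2, 3, 4)
  tab <- cbind(base, base + 1, base)   # observer 2 offset by a constant
  expect_equal(icc(tab), 5 / 6, tolerance = 1e-12)  # hand-computed mean squares
  expect_equal(icc(tab), icc_aov_oracle(tab), tolerance = 1e-9)
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(rnorm(5 * 3, 20, 4), 5, 3) + rnorm(5)
    expect_equal(icc(m), icc_aov_oracle(m), tolerance = 1e-9)
  }
})

test_that("pairwise observer correlations are 1 for identical columns", {
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(2, 4, 6, 8))
  r <- observer_correlations(m)
  expect_named(r, c("r_12", "r_13", "r_23"))
  expect_equal(unname(r), c(1, 1, 1), tolerance = 1e-12)
})
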