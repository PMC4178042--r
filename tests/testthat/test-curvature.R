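# Signed local curvature: stencil values, coordinate conversion, resampling
# and the geometric invariances of the profile.

test_that("three-point stencil reproduces hand-computed values", {
  # collinear points have exactly zero curvature
  expect_identical(local_curvature(100, 150, 200), 0)
  expect_identical(local_curvature(0, 0, 0), 0)

  # a 25-um posterior pit over a 1000-um span: f'' = -50/500^2, f' = 0
  expect_equal(local_curvature(0, 25, 0), -2e-4)

  # apex of a posterior bowl of radius 2000 um: exact circle depths through
  # the stencil arithmetic, evaluated longhand as the independent oracle
  f <- function(s) sqrt(2000^2 - s^2) - 2000
  d1 <- (f(500) - f(-500)) / (2 * 500)
  d2 <- (f(500) - 2 * f(0) + f(-500)) / 500^2
  oracle <- d2 / (1 + d1^2)^1.5
  expect_equal(local_curvature(f(-500), f(0), f(500), 500), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, -5.0806662e-4, tolerance = 1e-7 / 5e-4)

  expect_error(local_curvature(1, NA, 2), "non-finite")
})

test_that("to_physical applies the anisotropic pixel calibration", {
  n <- 201
  depth <- rep(50, n)
  tr <- boundary_trace(depth, layer = "BM")
  pt <- to_physical(tr, calibration(10, 10), center_col = 101)
  expect_equal(pt$position_um[201], 1000)   # 100 columns right of center
  expect_equal(pt$depth_um[201], 500)

  # a 45-degree line in pixel space has slope axial/lateral in um space
  tr2 <- boundary_trace(seq_len(n), layer = "BM")
  pt2 <- to_physical(tr2, calibration(5, 20), center_col = 101)
  expect_equal(diff(pt2$depth_um) / diff(pt2$position_um), rep(0.25, n - 1))

  # identity under isotropic unit calibration
  pt3 <- to_physical(tr2, calibration(1, 1), center_col = 1)
  expect_equal(pt3$depth_um, as.numeric(seq_len(n)))

  expect_error(to_physical(boundary_trace(c(1, NA, NA), c(TRUE, FALSE, FALSE)),
                           calibration(1, 1), 1),
               "fewer than 2 valid")
})

test_that("dense resampling interpolates linearly and respects gaps", {
  tr <- physical_trace(c(0, 1000), c(0, 100))
  rs <- resample_dense(tr)
  expect_length(rs$position_um, 1001)
  expect_equal(rs$depth_um, seq(0, 100, by = 0.1))

  # values at original nodes are preserved
  tr2 <- physical_trace(seq(0, 100, by = 1), sin(seq(0, 100, by = 1) / 10))
  rs2 <- resample_dense(tr2)
  expect_equal(rs2$depth_um, tr2$depth_um)

  # a 2000-um hole between valid spans stays invalid
  pos <- c(seq(0, 1000, 100), seq(3000, 4000, 100))
  tr3 <- physical_trace(pos, rep(0, length(pos)))
  rs3 <- resample_dense(tr3)
  expect_false(any(rs3$valid[rs3$position_um > 1000 & rs3$position_um < 3000]))
  expect_true(all(rs3$valid[rs3$position_um <= 1000]))
})

test_that("curvature profile trims stencil margins and recovers circles", {
  # straight trace of arbitrary slope: zero curvature everywhere valid
  nodes <- seq(-4500, 4500, by = 500)
  tr <- resample_dense(physical_trace(nodes, 40 * nodes / 1000 - 90))
  p <- curvature_profile(tr)
  expect_gt(sum(p$valid), 0)
  # zero up to interpolation roundoff (exact zero is asserted for exactly
  # collinear stencil inputs in the local_curvature tests)
  expect_lt(max(abs(p$kappa[p$valid])), 1e-17)

  # a full 9-mm line evaluates over 8 mm: 500 um trimmed per side
  expect_equal(range(p$position_um[p$valid]), c(-4000, 4000))

  # circle sections recover kappa = -1/R within 2% at every interior point
  for (spec in list(c(2000, 1500), c(5000, 3000), c(13000, 4500))) {
    R <- spec[1]
    s <- seq(-spec[2], spec[2], by = 1)
    prof <- curvature_profile(physical_trace(s, sqrt(R^2 - s^2) - R))
    expect_true(all(abs(prof$kappa[prof$valid] * R + 1) < 0.02),
                label = sprintf("circle R = %g recovered", R))
  }

  # shorter than the stencil span: empty profile with a warning
  short <- resample_dense(physical_trace(c(0, 800), c(0, 0)))
  expect_warning(pe <- curvature_profile(short), "shorter")
  expect_false(any(pe$valid))
})

test_that("curvature is invariant to translation and reflection, odd in depth", {
  set.seed(7)
  for (rep in 1:5) {
    tr <- random_smooth_trace()
    p0 <- curvature_profile(tr)
    # axial translation
    p1 <- curvature_profile(physical_trace(tr$position_um, tr$depth_um + 137))
    expect_equal(p1$kappa, p0$kappa)
    # left-right reflection
    p2 <- curvature_profile(physical_trace(tr$position_um, rev(tr$depth_um)))
    expect_equal(p2$kappa, rev(p0$kappa))
    # flipping depth sign flips the curvature sign
    p3 <- curvature_profile(physical_trace(tr$position_um, -tr$depth_um))
    expect_equal(p3$kappa, -p0$kappa)
  }
})

test_that("stencil error on smooth traces shrinks like h^2", {
  R <- 8000
  s <- seq(-2000, 2000, by = 1)
  tr <- physical_trace(s, sqrt(R^2 - s^2) - R)
  err <- vapply(c(500, 250, 125), function(h) {
    p <- curvature_profile(tr, h_um = h)
    abs(p$kappa[p$position_um == 0] + 1 / R)
  }, numeric(1))
  # halving h cuts the apex error by about 4 (second-order stencil)
  expect_gt(err[1] / err[2], 3)
  expect_gt(err[2] / err[3], 3)
})
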