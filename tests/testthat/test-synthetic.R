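# Phantom generator: surfaces, radial traces, B-scan rendering, cohorts.

test_that("surface depth follows the spherical cap plus Gaussian features", {
  sph <- surface_model("sphere")
  expect_equal(surface_depth(sph, 0, 0), 0)
  # off-axis the globe wall moves anteriorly: depth is negative
  expect_equal(surface_depth(sph, 3000, 0), sqrt(13000^2 - 3000^2) - 13000)
  expect_equal(surface_depth(sph, 3000, 0), -350.88936, tolerance = 1e-7)
  expect_equal(surface_depth(sph, 0, 3000), surface_depth(sph, 3000, 0))

  # staphyloma bowl adds its full height at the centre
  st <- surface_model("staphyloma", bowl_depth_um = 600, bowl_sigma_um = 2000)
  expect_equal(surface_depth(st, 0, 0), 600)
  # and decays following the Gaussian
  expect_equal(surface_depth(st, 2000, 0) - surface_depth(sph, 2000, 0),
               600 * exp(-0.5))

  expect_error(surface_depth(sph, 13000, 0), "outside the base sphere")
})

test_that("radial traces sample the surface along each scan line", {
  sph <- surface_model("sphere")
  trs <- sample_radial_traces(sph, 12, 4500, 500)
  expect_length(trs, 12)
  expect_equal(vapply(trs, attr, numeric(1), "angle_deg"), seq(0, 165, by = 15))
  # 19 samples across +-4500 at 500-um steps
  expect_length(trs[[1]]$position_um, 19L)
  # rotational symmetry: all traces identical
  for (t in trs[-1]) expect_equal(t$depth_um, trs[[1]]$depth_um)

  # an offset bowl is deepest along the ray through the offset
  off <- surface_model("staphyloma", center_offset_um = c(1200, 0))
  trs2 <- sample_radial_traces(off, 12, 4500, 100)
  deepest <- which.max(vapply(trs2, function(t) max(t$depth_um), numeric(1)))
  expect_equal(attr(trs2[[deepest]], "angle_deg"), 0)
})

test_that("B-scan rendering is seed-deterministic with exact noiseless bands", {
  r <- flat_render()
  px <- r$scan$pixels
  gt <- unique(r$gt_bm_px)
  expect_length(gt, 1L)
  maxv <- 65535
  # bright BM band immediately anterior to the ground-truth row, half-edge on it
  expect_equal(unique(px[gt - 1, ]), as.integer(round(0.90 * maxv)))
  expect_equal(unique(px[gt, ]), as.integer(round((0.90 + 0.12) / 2 * maxv)))
  expect_equal(unique(px[gt + 1, ]), as.integer(round(0.12 * maxv)))

  s1 <- render_bscan(flat_trace(), calibration(7, 15), speckle_sigma = 0.3, seed = 5)
  s2 <- render_bscan(flat_trace(), calibration(7, 15), speckle_sigma = 0.3, seed = 5)
  expect_identical(s1$scan$pixels, s2$scan$pixels)
  expect_false(identical(s1$scan$pixels, px))

  # speckle perturbs intensities but the band still dominates locally
  gt1 <- s1$gt_bm_px
  loc <- vapply(seq_len(ncol(px)), function(j) {
    w <- (gt1[j] - 10):min(nrow(px), gt1[j] + 6)
    w[which.max(s1$scan$pixels[w, j])]
  }, numeric(1))
  expect_gt(mean(loc >= gt1 - 3 & loc <= gt1 - 1), 0.95)

  expect_error(render_bscan(flat_trace(), calibration(7, 15), n_rows = 30),
               "exceeds image depth")
})

test_that("cohort generation is deterministic with faithful ground truth", {
  groups <- list(
    list(label = "flat", n = 10, kind = "sphere",
         base_radius_um = c(13000, 500)),
    list(label = "staphyloma", n = 10, kind = "staphyloma",
         base_radius_um = c(13000, 500), bowl_depth_um = c(800, 100),
         bowl_sigma_um = 1500))
  co <- generate_cohort(groups, seed = 9)
  expect_length(co, 20L)
  expect_equal(vapply(co, `[[`, character(1), "label"),
               rep(c("flat", "staphyloma"), each = 10))

  # spheres have constant curvature: ground-truth variance is numerically zero
  vflat <- vapply(co[1:10], function(e) e$truth$var_kappa, numeric(1))
  expect_true(all(vflat < 1e-12))
  # bowls curve more than spheres on average
  m_flat <- mean(vapply(co[1:10], function(e) e$truth$mean_abs_kappa, numeric(1)))
  m_st <- mean(vapply(co[11:20], function(e) e$truth$mean_abs_kappa, numeric(1)))
  expect_gt(m_st, m_flat)

  co2 <- generate_cohort(groups, seed = 9)
  expect_equal(vapply(co2, function(e) e$truth$mean_abs_kappa, numeric(1)),
               vapply(co, function(e) e$truth$mean_abs_kappa, numeric(1)))
  expect_error(generate_cohort(list()), "zero groups")
})

test_that("noiseless phantom pipeline curvature matches the analytic surface", {
  # feature scales well above the 500-um stencil arm: analytic agreement to 2%
  m <- surface_model("staphyloma", bowl_depth_um = 600, bowl_sigma_um = 2000)
  tr <- sample_radial_traces(m, 1, 4500, 1)[[1]]
  p <- curvature_profile(tr)
  s <- p$position_um[p$valid]
  # analytic curvature of the section: kappa = z'' / (1 + z'^2)^(3/2)
  R <- 13000
  z1 <- -s / sqrt(R^2 - s^2) - 600 * s / 2000^2 * exp(-s^2 / (2 * 2000^2))
  z2 <- -R^2 / (R^2 - s^2)^1.5 +
    600 * (s^2 / 2000^4 - 1 / 2000^2) * exp(-s^2 / (2 * 2000^2))
  kan <- z2 / (1 + z1^2)^1.5
  expect_lt(max(abs(p$kappa[p$valid] - kan) / max(abs(kan))), 0.02)
})
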