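# Filter cascade, boundary detection, snake refinement, manual corrections.

test_that("median denoising removes impulses and keeps flat regions", {
  # constant image is (numerically) unchanged
  m <- matrix(10, 7, 7)
  expect_equal(oct_denoise(m), m, tolerance = 1e-3)
  # single impulse on flat background is removed
  imp <- matrix(10, 7, 7); imp[4, 4] <- 100
  expect_equal(oct_denoise(imp)[4, 4], 10, tolerance = 1e-3)
  # 3x3 of 1..9: the centre becomes the median 5
  expect_equal(oct_denoise(matrix(1:9, 3, 3))[2, 2], 5, tolerance = 1e-3)
  expect_error(oct_denoise(matrix(1, 2, 2), size = 2), "larger than the image")
})

test_that("ridge filter prefers horizontal bright bands", {
  # uniform image: zero response up to FFT roundoff
  expect_lt(max(layer_response(matrix(3, 30, 30))), 1e-10)
  hline <- matrix(0, 31, 31); hline[16, ] <- 1
  resp <- layer_response(hline)
  expect_true(all(apply(resp[, 5:27], 2, which.max) == 16))
  vline <- matrix(0, 31, 31); vline[, 16] <- 1
  expect_gt(max(resp), max(layer_response(vline)))
})

test_that("Sobel depth gradient is signed increasing-with-depth", {
  expect_lt(max(abs(gradient_response(matrix(2, 10, 10)))), 1e-10)
  step <- matrix(0, 20, 9); step[11:20, ] <- 1
  g <- gradient_response(step)
  expect_true(all(g[10:11, 5] > 0))
  expect_equal(which.max(g[, 5]) %in% c(10L, 11L), TRUE)
  expect_equal(gradient_response(1 - step), -g)
})

test_that("boundary detection is exact on noiseless phantoms", {
  r <- flat_render()
  b <- detect_boundaries(r$scan)
  expect_true(all(b$bm$valid))
  expect_equal(b$bm$depth_px, as.numeric(r$gt_bm_px))
  # ILM sits one nominal retinal thickness anterior to the BM
  expect_equal(unique(b$ilm$depth_px),
               unique(r$gt_bm_px) - ceiling(350 / 7))
  # NFL boundary lies posterior to the ILM
  expect_true(all(b$nfl$depth_px > b$ilm$depth_px))
})

test_that("boundary detection stays within 2 rows under speckle", {
  ph <- staph_eye_101()
  s <- ph$set$scans[[1]]
  b <- detect_boundaries(s)
  v <- b$bm$valid
  rmse <- sqrt(mean((b$bm$depth_px - ph$gt_bm_px[[1]])[v]^2))
  expect_lt(rmse, 2)
  expect_gt(mean(v), 0.95)
})

test_that("columns with no supra-threshold layer peak are invalid", {
  r <- flat_render()
  px <- r$scan$pixels
  px[, 290:310] <- as.integer(round(0.02 * 65535))  # wipe all structure
  b <- detect_boundaries(px)
  expect_false(b$bm$valid[300])
  expect_true(b$bm$valid[50])
  # a structureless image (no layer peaks anywhere) fails loudly
  expect_error(suppressWarnings(detect_boundaries(matrix(7, 30, 40))),
               "segmentation failure")
})

test_that("detection is local: distant image edits do not move the BM", {
  r <- flat_render()
  px <- r$scan$pixels
  px2 <- px
  px2[, 500:601] <- as.integer(round(0.02 * 65535))
  b1 <- detect_boundaries(px)
  b2 <- detect_boundaries(px2)
  expect_equal(b1$bm$depth_px[1:450], b2$bm$depth_px[1:450])
})

test_that("snake refinement lowers energy monotonically and converges", {
  r <- flat_render()
  gt <- r$gt_bm_px[1]
  edge <- pmax(-gradient_response(oct_denoise(r$scan$pixels)), 0)
  # zigzag initialisation on a straight band converges onto the band
  zig <- boundary_trace(gt + rep(c(-2, 2), length.out = 601), layer = "BM")
  ref <- refine_snakes(zig, r$scan$pixels, snake_params(iterations = 500),
                       response = edge)
  expect_lt(max(abs(ref$depth_px - gt)), 1)
  e <- attr(ref, "energy")
  expect_true(all(diff(e) <= 1e-9 * (1 + abs(e[-length(e)]))))

  # a trace already on the band is a fixed point
  straight <- boundary_trace(rep(gt, 601), layer = "BM")
  ref2 <- refine_snakes(straight, r$scan$pixels, response = edge)
  expect_equal(ref2$depth_px, straight$depth_px)

  # manually pinned columns never move
  pinned <- boundary_trace(c(rep(gt, 300), gt - 10, rep(gt, 300)),
                           manual = c(rep(FALSE, 300), TRUE, rep(FALSE, 300)),
                           layer = "BM")
  ref3 <- refine_snakes(pinned, r$scan$pixels, response = edge)
  expect_equal(ref3$depth_px[301], gt - 10)
  expect_true(ref3$manual[301])
})

test_that("manual corrections overwrite, validate and flag exactly", {
  tr <- boundary_trace(rep(20, 50), layer = "BM")
  expect_equal(apply_corrections(tr, NULL), tr)
  expect_equal(apply_corrections(tr, data.frame(column = integer(0),
                                                depth_px = numeric(0))), tr)

  # a realistic manual load: ten re-plotted points per slice
  corr <- data.frame(column = seq(2, 47, by = 5), depth_px = 25)
  out <- apply_corrections(tr, corr)
  expect_equal(sum(out$manual), 10L)
  expect_equal(out$depth_px[corr$column], rep(25, 10))
  expect_equal(out$depth_px[-corr$column], rep(20, 40))

  # correcting an invalid column makes it valid and manual
  tri <- boundary_trace(c(NA, rep(20, 9)), valid = c(FALSE, rep(TRUE, 9)),
                        layer = "BM")
  out2 <- apply_corrections(tri, data.frame(column = 1, depth_px = 18))
  expect_true(out2$valid[1] && out2$manual[1])
  expect_equal(out2$depth_px[1], 18)

  expect_error(apply_corrections(tr, data.frame(column = 99, depth_px = 1)),
               "out of range")
})
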