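test_that("ROI ratios behave on synthetic two-channel stacks", {
  ## channel A identical to channel B: every ratio is exactly 1
  set.seed(5)
  base <- renderIhcPair(1, renderParams(n_slices = 4), seed = 3)
  v <- base@voxels
  v[, , , 1] <- v[, , , 2]
  eq <- new("ImageStack", voxels = v, pixelSize = base@pixelSize,
            zStep = 1, origin = base@origin)
  m <- measureRois(eq, ihcParams(seed = 9))
  expect_equal(m$mean_ratio, 1, tolerance = 1e-12)
  expect_equal(m$sd_ratio, 0, tolerance = 1e-12)

  ## channel A all zero: ratio 0
  v[, , , 1] <- 0
  z <- new("ImageStack", voxels = v, pixelSize = base@pixelSize,
           zStep = 1, origin = base@origin)
  expect_equal(measureRois(z, ihcParams(seed = 9))$mean_ratio, 0)
})

test_that("the structural channel is identical across expression levels", {
  a <- renderIhcPair(1.0, renderParams(n_slices = 4), seed = 21)
  b <- renderIhcPair(0.05, renderParams(n_slices = 4), seed = 21)
  expect_identical(a@voxels[, , , 2], b@voxels[, , , 2])
  expect_false(identical(a@voxels[, , , 1], b@voxels[, , , 1]))
})

test_that("ROI ratios scale linearly with expression level", {
  ## factor-20 construction: expression 1.0 vs 0.05 with the same seed
  hi <- renderIhcPair(1.0, renderParams(n_slices = 6), seed = 33)
  lo <- renderIhcPair(0.05, renderParams(n_slices = 6), seed = 33)
  mh <- measureRois(hi, ihcParams(seed = 2))
  ml <- measureRois(lo, ihcParams(seed = 2))
  expect_equal(mh$mean_ratio / ml$mean_ratio, 20, tolerance = 0.1 * 20)
  ## monotone in expression
  mid <- measureRois(renderIhcPair(0.4, renderParams(n_slices = 6), seed = 33),
                     ihcParams(seed = 2))
  expect_gt(mh$mean_ratio, mid$mean_ratio)
  expect_gt(mid$mean_ratio, ml$mean_ratio)
})

test_that("ratios are invariant to a common intensity rescaling", {
  st <- renderIhcPair(0.6, renderParams(n_slices = 4), seed = 8)
  half <- new("ImageStack", voxels = st@voxels * 0.5,
              pixelSize = st@pixelSize, zStep = 1, origin = st@origin)
  m1 <- measureRois(st, ihcParams(seed = 4))
  m2 <- measureRois(half, ihcParams(seed = 4))
  expect_equal(m1$mean_ratio, m2$mean_ratio, tolerance = 1e-9)
})

test_that("the ROI report writes one row per ROI plus a summary", {
  st <- renderIhcPair(0.5, renderParams(n_slices = 4), seed = 6)
  m <- measureRois(st, ihcParams(n_rois = 4, seed = 1))
  expect_equal(nrow(m$rois), 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeIhcReport(m, path)
  rep <- utils::read.csv(path)
  expect_equal(nrow(rep), 5L)
  expect_equal(rep$ratio[5], m$mean_ratio, tolerance = 1e-9)
})
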