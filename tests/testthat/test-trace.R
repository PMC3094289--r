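test_that("projection and segmentation recover a rendered branch", {
  tree <- straightTree(len = 100)
  st <- renderStack(tree, renderParams(noise_sd = 0))
  seg <- projectAndSegment(st)
  expect_true(any(seg$mask))
  ## one connected component
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(seg$mask)))
  expect_equal(max(lab), 1)
  ## default-noise mask area close to the noise-free one
  set.seed(10)
  stn <- renderStack(tree, renderParams())
  segn <- projectAndSegment(stn)
  expect_lt(abs(sum(segn$mask) - sum(seg$mask)) / sum(seg$mask), 0.15)
  ## pure background errors out
  empty <- new("ArborTree")
  stbg <- renderStack(empty, renderParams(noise_sd = 0))
  expect_error(projectAndSegment(stbg), "no axon found")
})

test_that("noise-free round trip recovers structure and length within 5%", {
  ## straight branch: 1 branch, arc length ~100
  tree <- straightTree(len = 100)
  st <- renderStack(tree, renderParams(noise_sd = 0))
  tr <- traceStack(st, entry_hint = tree@entryPoint)
  expect_equal(nBranches(tr), 1L)
  expect_lt(abs(sum(branchLengths(tr)) - 100) / 100, 0.05)

  ## Y-shaped arbor: 3 branches; per-branch error within 5% or the ~1.5 um
  ## pixel/junction quantization floor, whichever is larger; the total stays
  ## within 5%
  y <- yTree()
  sty <- renderStack(y, renderParams(noise_sd = 0))
  try_ <- traceStack(sty, entry_hint = y@entryPoint)
  expect_equal(nBranches(try_), 3L)
  gtl <- sort(branchLengths(y))
  trl <- sort(branchLengths(try_))
  expect_true(all(abs(trl - gtl) < pmax(0.05 * gtl, 1.5)))
  expect_lt(abs(sum(trl) - sum(gtl)) / sum(gtl), 0.05)
  expect_true(validObject(try_))
})

test_that("varicosity detection finds separated blobs at their positions", {
  tree <- straightTree(len = 100)
  b <- tree@branches[[1]]
  b@varicosities <- data.frame(arc_position = c(20, 50, 80),
                               diameter = rep(3.4, 3),
                               intensity_gain = rep(2.6, 3))
  tree@branches <- list(b)
  st <- renderStack(tree, renderParams(noise_sd = 0))
  tr <- traceStack(st, entry_hint = tree@entryPoint)
  v <- tr@branches[[1]]@varicosities
  expect_equal(nrow(v), 3L)
  expect_true(all(abs(sort(v$arc_position) - c(20, 50, 80)) < 2))

  ## a uniform-width noise-free axon has no detections
  plain <- straightTree(len = 100)
  stp <- renderStack(plain, renderParams(noise_sd = 0))
  trp <- traceStack(stp, entry_hint = plain@entryPoint)
  expect_equal(nVaricosities(trp), 0L)
})

test_that("raising the intensity factor never increases detections", {
  cfg <- calibrated("w-")
  set.seed(17)
  arb <- sampleArbor(cfg, wildtypeTemplate(), check = FALSE)
  st <- renderStack(arb)
  seg <- projectAndSegment(st)
  counts <- vapply(c(1.2, 1.5, 2.0, 3.0), function(f) {
    p <- traceParams(varicosity_intensity_factor = f)
    tr <- extractTree(seg$mask, seg$projection, arb@branches[[1]]@polyline[1, ],
                      p, st@pixelSize, st@origin)
    nVaricosities(detectVaricosities(seg$projection, tr, seg$mask, p,
                                     st@pixelSize, st@origin))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("recovered lengths are robust to pixel size", {
  ## doubling the pixel size changes recovered micrometer lengths by <5%
  tree <- straightTree(len = 100)
  l1 <- sum(branchLengths(traceStack(
    renderStack(tree, renderParams(noise_sd = 0, pixel_size = 0.5)),
    entry_hint = tree@entryPoint)))
  l2 <- sum(branchLengths(traceStack(
    renderStack(tree, renderParams(noise_sd = 0, pixel_size = 1.0)),
    entry_hint = tree@entryPoint)))
  expect_lt(abs(l2 - l1) / l1, 0.05)
})

test_that("a coarse pixel grid flags degraded rendering", {
  tree <- straightTree()
  st <- renderStack(tree, renderParams(pixel_size = 2, noise_sd = 0))
  expect_true(st@degraded)
  expect_false(renderStack(tree, renderParams(noise_sd = 0))@degraded)
})

test_that("image stacks round-trip through TIFF with calibration", {
  tree <- yTree()
  set.seed(3)
  st <- renderStack(tree, renderParams(n_slices = 4))
  path <- withr::local_tempfile(fileext = ".tif")
  writeImageStack(st, path)
  back <- readImageStack(path)
  expect_equal(dim(back@voxels), dim(st@voxels))
  expect_equal(back@pixelSize, st@pixelSize)
  expect_equal(back@origin, st@origin, tolerance = 1e-9)
  ## 16-bit quantization
  expect_lt(max(abs(back@voxels - st@voxels)), 1e-4)
})
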