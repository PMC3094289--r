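test_that("the 4-um branch filter is strictly exclusive", {
  tree <- metricTree(lengths = c(30, 3.9, 4.0, 4.1), nvari = c(0, 1, 1, 1))
  ## width equals the reference: no rescaling, pure filtering; short branches
  ## are chained so survivors must re-anchor through kept ancestors only
  out <- filterAndNormalize(tree, morphometryParams(
    reference_ganglion_width = tree@ganglionWidth))
  kept <- branchLengths(out)
  expect_true(all(kept > 4))
  expect_true("b1" %in% names(kept))
  ## 3.9 and 4.0 go; 4.1 hangs off 4.0 so it is dropped with its parent
  expect_false(any(c("b2", "b3", "b4") %in% names(kept)))
})

test_that("normalization rescales lengths by the width ratio", {
  tree <- metricTree(lengths = c(10, 20), nvari = c(1, 3))
  tree@ganglionWidth <- 270     # twice the reference
  out <- filterAndNormalize(tree, morphometryParams(
    reference_ganglion_width = 135))
  expect_equal(unname(sort(branchLengths(out))), c(5, 10), tolerance = 1e-9)
  expect_error(filterAndNormalize({
    t2 <- tree; t2@ganglionWidth <- -1; t2
  }), "positive")
})

test_that("filtering is idempotent", {
  cfg <- calibrated("w-")
  set.seed(21)
  arb <- sampleArbor(cfg, wildtypeTemplate(), check = FALSE)
  p <- morphometryParams(reference_ganglion_width = 135)
  once <- filterAndNormalize(arb, p)
  twice <- filterAndNormalize(once, p)
  expect_equal(branchLengths(twice), branchLengths(once), tolerance = 1e-12)
  expect_equal(twice@ganglionWidth, once@ganglionWidth)
})

test_that("empty trees pass through the filter", {
  empty <- new("ArborTree", ganglionWidth = 120)
  out <- filterAndNormalize(empty, morphometryParams(
    reference_ganglion_width = 135))
  expect_equal(nBranches(out), 0L)
})

test_that("summarizeArbor computes the advertised arithmetic", {
  tree <- metricTree(lengths = c(10, 20), nvari = c(1, 3))
  m <- summarizeArbor(tree)
  expect_equal(m$branch_count, 2L)
  expect_equal(m$total_length, 30, tolerance = 1e-9)
  expect_equal(m$varicosity_count, 4L)
  expect_equal(m$varicosities_per_branch, 2)
  empty <- summarizeArbor(new("ArborTree"))
  expect_equal(empty$varicosities_per_branch, 0)
})

test_that("total length is invariant to branch order and resampling", {
  cfg <- calibrated("w-")
  set.seed(8)
  arb <- sampleArbor(cfg, wildtypeTemplate(), check = FALSE)
  tot <- sum(branchLengths(arb))
  shuffled <- arb
  ## reorder leaving the root first (validity requires parents before use)
  ord <- c(1, rev(seq_along(arb@branches)[-1]))
  shuffled@branches <- arb@branches[ord]
  expect_equal(sum(branchLengths(shuffled)), tot, tolerance = 1e-12)
  ## resampling invariance on piecewise-straight geometry (linear
  ## interpolation is exact there; on curved polylines it is a discretization)
  mt <- metricTree(lengths = c(30, 22, 15), nvari = c(0, 0, 0))
  mtot <- sum(branchLengths(mt))
  resampled <- sum(vapply(branches(mt), function(b)
    polylineLength(resamplePolyline(b@polyline, 0.25)), numeric(1)))
  expect_equal(resampled, mtot, tolerance = 1e-3)
})

test_that("removing a branch never increases the varicosity count", {
  tree <- metricTree(lengths = c(30, 12, 8), nvari = c(2, 3, 1))
  full <- summarizeArbor(tree)
  pruned <- tree
  pruned@branches <- tree@branches[1:2]
  expect_lte(summarizeArbor(pruned)$varicosity_count, full$varicosity_count)
})
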