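test_that("degenerate configurations produce the promised arbors", {
  tpl <- wildtypeTemplate()
  ## all presence probs 1, no variable branches, no routing errors
  b <- templateBranches(tpl)
  b$presence_prob <- 1
  allp <- makeTemplate(b, freq_threshold = 0.8)
  cfg <- calibrated("w-")
  cfg@variableBranchRate <- 0
  cfg@variableBranchSD <- 0
  cfg@routingErrorRate <- 0
  set.seed(1)
  arb <- sampleArbor(cfg, allp, check = FALSE)
  expect_equal(nBranches(arb), 16L)
  expect_true(all(startsWith(branchLabels(arb), "skeletal:")))
  expect_true(validObject(arb))

  ## zero varicosity density
  cfg0 <- cfg
  cfg0@varicosityDensity <- 0
  set.seed(2)
  expect_equal(nVaricosities(sampleArbor(cfg0, allp, check = FALSE)), 0L)
})

test_that("cohorts are reproducible bit for bit under a fixed seed", {
  tpl <- wildtypeTemplate()
  cfg <- calibrated("w-")
  a <- sampleCohort(cfg, tpl, seed = 77, n = 3)
  b <- sampleCohort(cfg, tpl, seed = 77, n = 3)
  expect_length(a, 3L)
  ## byte-identical SWC serialization
  fa <- withr::local_tempfile(fileext = ".swc")
  fb <- withr::local_tempfile(fileext = ".swc")
  for (i in 1:3) {
    writeSWC(a[[i]], fa)
    writeSWC(b[[i]], fb)
    expect_identical(readLines(fa), readLines(fb))
  }
  ## and a different seed changes the draw
  c1 <- sampleCohort(cfg, tpl, seed = 78, n = 1)
  writeSWC(a[[1]], fa); writeSWC(c1[[1]], fb)
  expect_false(identical(readLines(fa), readLines(fb)))
})

test_that("branch lengths equal polyline arc lengths", {
  cfg <- calibrated("PlexA-RNAi")
  set.seed(5)
  arb <- sampleArbor(cfg, wildtypeTemplate(), check = FALSE)
  for (b in branches(arb))
    expect_equal(b@length, polylineLength(b@polyline),
                 tolerance = 1e-6)
  expect_true(validObject(arb))
})

test_that("expected counts are monotone in their driving rates", {
  tpl <- wildtypeTemplate()
  cfg <- calibrated("w-")
  ## varicosity count nondecreasing in varicosity density (analytically and
  ## in simulation)
  lo <- cfg; lo@varicosityDensity <- 0.01
  hi <- cfg; hi@varicosityDensity <- 0.05
  expect_lte(expectedMoments(lo, tpl)$varicosity_mean,
             expectedMoments(hi, tpl)$varicosity_mean)
  set.seed(9)
  vlo <- mean(replicate(25, nVaricosities(sampleArbor(lo, tpl, check = FALSE))))
  set.seed(9)
  vhi <- mean(replicate(25, nVaricosities(sampleArbor(hi, tpl, check = FALSE))))
  expect_lte(vlo, vhi)
  ## branch count nondecreasing in the variable-branch rate
  blo <- cfg; blo@variableBranchRate <- 2; blo@variableBranchSD <- 0.5
  bhi <- cfg; bhi@variableBranchRate <- 9; bhi@variableBranchSD <- 0.5
  set.seed(4)
  nlo <- mean(replicate(25, nBranches(sampleArbor(blo, tpl, check = FALSE))))
  set.seed(4)
  nhi <- mean(replicate(25, nBranches(sampleArbor(bhi, tpl, check = FALSE))))
  expect_lte(nlo, nhi)
})

test_that("hard-core varicosity placement is stationary with the right rate", {
  ## oracle: expected count of a stationary process on [0, L] is rate * L
  set.seed(31)
  for (case in list(c(len = 100, rate = 0.0312), c(len = 40, rate = 0.12))) {
    n <- replicate(3000,
                   length(arborquant:::.renewalPositions(case[["len"]],
                                                         case[["rate"]])))
    expect_equal(mean(n), case[["len"]] * case[["rate"]], tolerance = 0.05)
    ## hard core: no two positions closer than 3 um
    pos <- arborquant:::.renewalPositions(500, 0.2)
    expect_true(all(diff(pos) >= 3))
  }
})

test_that("guidance errors move the recorded entry into the metathoracic band", {
  cfg <- calibrated("PlexA-RNAi")
  cfg@guidanceErrorRate <- 1
  set.seed(3)
  arb <- sampleArbor(cfg, wildtypeTemplate(), check = FALSE)
  expect_true(arb@guidanceError)
  expect_identical(arb@entryRegion, "metathoracic")
  expect_true(classifyEntry(arb))
  cfg@guidanceErrorRate <- 0
  set.seed(3)
  arb2 <- sampleArbor(cfg, wildtypeTemplate(), check = FALSE)
  expect_false(classifyEntry(arb2))
})

test_that("SWC round trip preserves the tree", {
  cfg <- calibrated("w-")
  set.seed(12)
  arb <- sampleArbor(cfg, wildtypeTemplate(), check = FALSE)
  path <- withr::local_tempfile(fileext = ".swc")
  writeSWC(arb, path)
  back <- readSWC(path)
  expect_equal(nBranches(back), nBranches(arb))
  expect_equal(sort(branchLengths(back)), sort(branchLengths(arb)),
               tolerance = 1e-5)
  expect_equal(nVaricosities(back), nVaricosities(arb))
  expect_identical(branchLabels(back), branchLabels(arb))
  expect_equal(back@ganglionWidth, arb@ganglionWidth, tolerance = 1e-5)
  expect_true(validObject(back))
})
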