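test_that("matching recovers an unperturbed skeleton and flags deletions", {
  tpl <- wildtypeTemplate()
  b <- templateBranches(tpl)
  b$presence_prob <- 1
  allp <- makeTemplate(b)
  cfg <- calibrated("w-")
  cfg@variableBranchRate <- 0; cfg@variableBranchSD <- 0
  cfg@routingErrorRate <- 0
  set.seed(14)
  arb <- filterAndNormalize(sampleArbor(cfg, allp, check = FALSE),
                            morphometryParams(reference_ganglion_width = 135))
  m <- matchToTemplate(arb, tpl)
  expect_equal(sum(!is.na(m$assignments)), 16L)
  expect_length(m$unmatched_observed, 0L)

  ## delete three skeletal branches (with no descendants): their template
  ## ids go unmatched
  drop <- c("b06", "b12", "b16")
  pruned <- arb
  pruned@branches <- Filter(function(b) !(b@id %in% drop), arb@branches)
  m2 <- matchToTemplate(pruned, tpl)
  expect_equal(sum(is.na(m2$assignments)), 3L)
  expect_setequal(names(m2$assignments)[is.na(m2$assignments)], drop)
})

test_that("matching an empty tree leaves everything unmatched at cost 0", {
  m <- matchToTemplate(new("ArborTree"), wildtypeTemplate())
  expect_true(all(is.na(m$assignments)))
  expect_equal(m$cost, 0)
})

test_that("hierarchical matching agrees with the exhaustive assignment oracle", {
  ## small instances: <= 6 branches per tree, brute-force per-brood
  ## enumeration must give identical assignments and costs
  tpl <- wildtypeTemplate()
  b <- templateBranches(tpl)[1:5, ]   # b01, b02, b03 + two grandchildren
  small <- makeTemplate(b)
  cfg <- calibrated("w-")
  cfg@variableBranchRate <- 2; cfg@variableBranchSD <- 0.5
  for (sd in 1:6) {
    set.seed(sd)
    arb <- sampleArbor(cfg, small, check = FALSE)
    arb <- filterAndNormalize(arb,
                              morphometryParams(reference_ganglion_width = 135))
    fast <- matchToTemplate(arb, small)
    slow <- matchToTemplate(arb, small, exhaustive = TRUE)
    expect_identical(fast$assignments, slow$assignments)
    expect_equal(fast$cost, slow$cost, tolerance = 1e-9)
  }
})

test_that("classification reproduces generator labels on unperturbed cohorts", {
  tpl <- wildtypeTemplate()
  cfg <- calibrated("w-")
  cfg@routingErrorRate <- 0
  co <- filterCohort(sampleCohort(cfg, tpl, seed = 55, n = 12))
  acc <- vapply(co, function(tree) {
    cl <- classifyBranches(tree, tpl)
    mean(startsWith(branchLabels(tree), "skeletal:") ==
           startsWith(branchLabels(cl$tree), "skeletal:"))
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
  ## count identities
  cl <- classifyBranches(co[[1]], tpl)
  expect_equal(cl$n_skeletal + cl$n_missing_skeletal, 16L)
  expect_equal(cl$n_skeletal + cl$n_variable, nBranches(co[[1]]))
  ## empty tree: all counts zero except missing
  cl0 <- classifyBranches(new("ArborTree"), tpl)
  expect_equal(cl0$n_skeletal, 0L)
  expect_equal(cl0$n_variable, 0L)
  expect_equal(cl0$n_missing_skeletal, 16L)
})

test_that("the consensus frequency threshold is strictly greater than 80%", {
  ## direct frequency count: a branch present in 17/21 arbors (81.0%) stays,
  ## one present in 16/21 (76.2%) goes
  tpl <- wildtypeTemplate()
  cfg <- calibrated("w-")
  cfg@variableBranchRate <- 0; cfg@variableBranchSD <- 0
  cfg@routingErrorRate <- 0
  b <- templateBranches(tpl); b$presence_prob <- 1
  allp <- makeTemplate(b)
  set.seed(99)
  co <- lapply(1:21, function(i) sampleArbor(cfg, allp, check = FALSE))
  co <- filterCohort(co)
  dropBranch <- function(tree, id) {
    tree@branches <- Filter(function(b) b@id != id, tree@branches)
    tree
  }
  ## b16 (a leaf) removed from 4 arbors -> 17/21; b12 removed from 5 -> 16/21
  for (i in 1:4) co[[i]] <- dropBranch(co[[i]], "b16")
  for (i in 1:5) co[[i]] <- dropBranch(co[[i]], "b12")
  cons <- buildConsensus(co)
  cb <- templateBranches(cons)
  expect_equal(nrow(cb), 15L)
  freqs <- sort(cb$presence_prob)
  expect_equal(freqs[1], 17 / 21, tolerance = 1e-9)
})

test_that("a single-arbor cohort is its own consensus", {
  cfg <- calibrated("w-")
  set.seed(4)
  arb <- filterAndNormalize(sampleArbor(cfg, wildtypeTemplate(),
                                        check = FALSE),
                            morphometryParams(reference_ganglion_width = 135))
  cons <- buildConsensus(list(arb))
  expect_equal(nrow(templateBranches(cons)), nBranches(arb))
  expect_true(all(templateBranches(cons)$presence_prob == 1))
})

test_that("consensus is invariant to cohort ordering", {
  tpl <- wildtypeTemplate()
  cfg <- calibrated("w-")
  co <- filterCohort(sampleCohort(cfg, tpl, seed = 31, n = 10))
  c1 <- buildConsensus(co)
  c2 <- buildConsensus(rev(co))
  b1 <- templateBranches(c1); b2 <- templateBranches(c2)
  expect_equal(nrow(b1), nrow(b2))
  expect_equal(sort(b1$mean_length), sort(b2$mean_length), tolerance = 1e-6)
  expect_equal(sort(b1$presence_prob), sort(b2$presence_prob),
               tolerance = 1e-9)
})

test_that("raising the frequency threshold never grows the consensus", {
  tpl <- wildtypeTemplate()
  cfg <- calibrated("w-")
  co <- filterCohort(sampleCohort(cfg, tpl, seed = 62, n = 12))
  sizes <- vapply(c(0.5, 0.8, 0.9), function(th)
    nrow(templateBranches(buildConsensus(co,
                                         consensusParams(freq_threshold = th)))),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("entry classification respects the region map", {
  t1 <- straightTree(from = c(30, 60))   # mesothoracic band
  expect_false(classifyEntry(t1))
  t2 <- straightTree(from = c(30, 60))
  t2@entryPoint <- c(30, 180)            # metathoracic band
  expect_true(classifyEntry(t2))
  t3 <- straightTree()
  t3@entryPoint <- c(30, 400)
  expect_error(classifyEntry(t3), "outside")
})
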