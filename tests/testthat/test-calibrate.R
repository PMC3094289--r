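test_that("truncated-normal moment formulas agree with numerical integration", {
  cases <- list(c(m = 13, s = 2.6, cut = 4), c(m = 40, s = 8, cut = 4),
                c(m = 8, s = 4, cut = 6))
  for (cs in cases) {
    got <- arborquant:::truncNormMoments(cs[["m"]], cs[["s"]], cs[["cut"]])
    dens <- function(x) stats::dnorm(x, cs[["m"]], cs[["s"]]) /
      stats::pnorm(cs[["m"]] / cs[["s"]])
    P <- stats::integrate(dens, cs[["cut"]], Inf)$value
    M1 <- stats::integrate(function(x) x * dens(x), cs[["cut"]], Inf)$value
    M2 <- stats::integrate(function(x) x^2 * dens(x), cs[["cut"]], Inf)$value
    expect_equal(got$P, P, tolerance = 1e-6)
    expect_equal(got$M1, M1, tolerance = 1e-6)
    expect_equal(got$M2, M2, tolerance = 1e-6)
  }
})

test_that("calibration reproduces the configured targets analytically", {
  tpl <- wildtypeTemplate()
  for (name in c("w-", "PlexB-RNAi", "PlexA-RNAi")) {
    cfg <- calibrated(name)
    mom <- expectedMoments(cfg, tpl)
    t <- cfg@targets
    expect_lt(abs(mom$branch_mean - t[["branch_mean"]]) / t[["branch_mean"]],
              0.01)
    expect_lt(abs(mom$total_len_mean - t[["total_len_mean"]]) /
                t[["total_len_mean"]], 0.01)
    expect_lt(abs(mom$varicosity_mean - t[["varicosity_mean"]]) /
                t[["varicosity_mean"]], 0.01)
    expect_true(checkCalibration(cfg, tpl))
  }
})

test_that("calibration is deterministic and flags infeasible targets", {
  tpl <- wildtypeTemplate()
  raw <- packagedGenotypes()[["w-"]]
  a <- calibrateConfig(raw, tpl)
  b <- calibrateConfig(raw, tpl)
  expect_identical(a@lengthScale, b@lengthScale)
  expect_identical(a@variableBranchRate, b@variableBranchRate)

  bad <- raw
  bad@targets[["skeletal_mean"]] <- 17      # above template capacity (16)
  expect_error(calibrateConfig(bad, tpl), "binding constraint")
  bad2 <- raw
  bad2@targets[["branch_mean"]] <- 10       # below skeletal_mean
  expect_error(calibrateConfig(bad2, tpl), "infeasible")
})

test_that("uncalibrated or mis-calibrated configurations are refused", {
  tpl <- wildtypeTemplate()
  raw <- packagedGenotypes()[["w-"]]
  expect_error(sampleArbor(raw, tpl), "not calibrated")
  off <- calibrated("w-")
  off@lengthScale <- off@lengthScale * 1.3   # expectations now off by >5%
  expect_error(checkCalibration(off, tpl), "calibration error")
})

test_that("all nine packaged configurations calibrate", {
  cfgs <- packagedGenotypes(calibrate = TRUE)
  expect_length(cfgs, 9L)
  expect_true(all(vapply(cfgs, function(c) c@calibrated, logical(1))))
  ## genotype config round trip through the key-value format
  path <- withr::local_tempfile(fileext = ".cfg")
  writeGenotypeConfig(cfgs[["PlexB-RNAi"]], path)
  back <- readGenotypeConfig(path)
  expect_equal(back@targets, cfgs[["PlexB-RNAi"]]@targets)
  expect_equal(back@lengthScale, cfgs[["PlexB-RNAi"]]@lengthScale,
               tolerance = 1e-9)
  expect_true(back@calibrated)
})
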