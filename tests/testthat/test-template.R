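test_that("packaged wildtype template has the stereotyped core structure", {
  tpl <- wildtypeTemplate()
  expect_s4_class(tpl, "SkeletonTemplate")
  expect_true(validObject(tpl))
  b <- templateBranches(tpl)
  expect_equal(nrow(b), 16L)
  expect_equal(min(b$mean_length), 13)
  expect_equal(max(b$mean_length), 151)
  expect_true(all(b$presence_prob >= 0.92))
  ## unit directions, valid tree, proper segment decomposition (every
  ## internal node hosts at least two daughters)
  expect_equal(unname(b$dir_x^2 + b$dir_y^2), rep(1, 16), tolerance = 1e-12)
  kids <- table(b$parent_id)
  expect_true(all(kids >= 2))
})

test_that("makeTemplate validates structure", {
  one <- data.frame(id = "r", parent_id = NA, attach_fraction = 0,
                    dir_x = 0, dir_y = 1, mean_length = 10, sd_length = 2,
                    presence_prob = 1)
  tpl <- makeTemplate(one)
  expect_equal(nrow(templateBranches(tpl)), 1L)
  expect_true(is.na(templateBranches(tpl)$parent_id))

  bad <- one
  bad$parent_id <- "ghost"
  expect_error(makeTemplate(bad), "unknown branch id")

  cyc <- rbind(
    data.frame(id = "a", parent_id = "b", attach_fraction = 1, dir_x = 1,
               dir_y = 0, mean_length = 5, sd_length = 1, presence_prob = 1),
    data.frame(id = "b", parent_id = "a", attach_fraction = 1, dir_x = 0,
               dir_y = 1, mean_length = 5, sd_length = 1, presence_prob = 1))
  expect_error(makeTemplate(cyc), "cyclic")

  neg <- one
  neg$mean_length <- -2
  expect_error(makeTemplate(neg), "positive")
})

test_that("templates round-trip through the plain-text format", {
  tpl <- wildtypeTemplate()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTemplate(tpl, path)
  back <- readTemplate(path)
  expect_equal(templateBranches(back), templateBranches(tpl),
               tolerance = 1e-9)
  expect_equal(back@freqThreshold, tpl@freqThreshold)
})

test_that("template geometry stays inside the imaging field", {
  geo <- templateGeometry(wildtypeTemplate())
  expect_true(all(geo$x1 >= 4 & geo$x1 <= 131))
  expect_true(all(geo$y1 >= 4 & geo$y1 <= 241))
  expect_equal(geo$depth[1], 0L)
  expect_true(all(geo$depth[-1] >= 1L))
})
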