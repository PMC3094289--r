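test_that("rank-sum test matches exhaustive enumeration at small n", {
  ## oracle: enumerate all group assignments of the pooled ranks
  bruteP <- function(x, y) {
    n1 <- length(x)
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * length(y) / 2
    combs <- utils::combn(length(r), n1)
    us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mean(abs(us - mu) >= abs(U - mu) - 1e-9)
  }
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    x <- sample(1:10, n, replace = TRUE)   # ties included
    y <- sample(1:10, n, replace = TRUE)
    got <- rankSumTest(x, y)
    expect_equal(got$p_value, bruteP(x, y), tolerance = 1e-12)
  }
  ## agreement with the reference implementation in the tie-free exact case
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(4.4, 6.2, 7.7, 0.3)
  expect_equal(rankSumTest(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
  ## complete separation pins U at 0
  expect_equal(rankSumTest(1:3, 4:6)$statistic, 0)
  expect_gte(rankSumTest(c(1, 2, 3), c(1, 2, 3))$p_value, 0.9)
  deg <- rankSumTest(rep(2, 4), rep(2, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  ## large-sample normal branch stays a probability
  set.seed(1)
  big <- rankSumTest(rnorm(40), rnorm(45, 0.5))
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("KS statistic equals the brute-force ECDF gap", {
  gapD <- function(x, y) {
    sup <- sort(unique(c(x, y)))
    max(abs(vapply(sup, function(s) mean(x <= s) - mean(y <= s), numeric(1))))
  }
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(sample(4:12, 1))
    y <- rnorm(sample(4:12, 1), 0.6)
    expect_equal(ksTest(x, y)$statistic, gapD(x, y), tolerance = 1e-12)
  }
  expect_equal(ksTest(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ksTest(c(1, 2), c(5, 6))$statistic, 1)
  expect_identical(ksTest(c(1, 2), c(3, 4, 5))$warning, "small sample")
})

test_that("chi-squared proportion test matches the closed form", {
  ## hand-computed sum((O-E)^2/E) on a fixed 2x2 table
  O <- rbind(c(5, 15), c(2, 28))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  byHand <- sum((O - E)^2 / E)
  got <- proportionTest(5, 20, 2, 30)
  expect_equal(got$statistic, byHand, tolerance = 1e-12)
  expect_equal(got$p_value,
               stats::pchisq(byHand, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  even <- proportionTest(5, 20, 5, 20)
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  expect_true(proportionTest(0, 21, 0, 21)$degenerate)
})

test_that("one-way ANOVA with Bonferroni behaves as specified", {
  g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(8, 9, 10, 11))
  res <- anovaBonferroni(g)
  ## F equals the between/within mean-square ratio computed by hand
  v <- unlist(g); f <- rep(names(g), each = 4)
  gm <- mean(v)
  ssb <- sum(4 * (tapply(v, f, mean) - gm)^2)
  ssw <- sum((v - ave(v, f))^2)
  expect_equal(res$anova$statistic, (ssb / 2) / (ssw / 9), tolerance = 1e-9)
  ## Bonferroni: adjusted p >= raw p, capped at 1
  for (pw in res$pairwise) {
    expect_gte(pw$p_value, pw$p_raw - 1e-15)
    expect_lte(pw$p_value, 1)
  }
  same <- anovaBonferroni(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_lt(same$anova$statistic, 1e-9)
  expect_equal(same$pairwise[[1]]$p_value, 1)
})

test_that("percent change reproduces simple arithmetic", {
  expect_equal(percentChange(150, 100)$percent, 50)
  expect_equal(percentChange(100, 100)$percent, 0)
  expect_error(percentChange(1, 0), "positive")
})

test_that("cohort table reports means, SEMs and guidance frequencies", {
  m1 <- data.frame(branch_count = c(22, 23), total_length = c(900, 920),
                   varicosity_count = c(28, 30),
                   varicosities_per_branch = c(1.2, 1.3),
                   n_skeletal = c(15, 16), n_variable = c(7, 7),
                   guidance_error = c(FALSE, TRUE))
  tab <- cohortTable(list(gA = m1, gB = m1[1, ]))
  expect_equal(tab$branch_mean[1], 22.5)
  expect_equal(tab$branch_sem[1], stats::sd(c(22, 23)) / sqrt(2))
  expect_equal(tab$guidance_error_freq[1], 0.5)
  ## single-arbor cohort: SEM 0 and flagged degenerate
  expect_equal(tab$branch_sem[2], 0)
  expect_true(tab$degenerate[2])
  expect_identical(tab$genotype, c("gA", "gB"))
})

test_that("length histograms bin in [k*w, (k+1)*w) and sum to one", {
  m <- data.frame(total_length = c(950, 950, 950))
  h <- lengthHistogram(m, 100)
  expect_equal(nrow(h), 1L)
  expect_equal(h$bin_lo, 900)
  expect_equal(h$frequency, 1)
  set.seed(2)
  m2 <- data.frame(total_length = runif(50, 500, 1500))
  expect_equal(sum(lengthHistogram(m2, 100)$frequency), 1)
  expect_error(lengthHistogram(m2[0, , drop = FALSE]), "empty")
})
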