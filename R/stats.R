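## Cohort statistics: the nonparametric battery and summary-table reporting.

.testResult <- function(statistic, p_value, method, adjusted = FALSE,
                        degenerate = FALSE, warning = NA_character_) {
  list(statistic = unname(statistic), p_value = unname(p_value),
       method = method, adjusted = adjusted, degenerate = degenerate,
       warning = warning)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null by enumeration over all rank arrangements (tie-aware) when
#' `n1 + n2 <= 12`, normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @return A test-result list: `statistic` (U for `x`), `p_value`, `method`,
#'   `adjusted`, `degenerate`.
#' @export
rankSumTest <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L)
    return(.testResult(U, 1, "mann-whitney", degenerate = TRUE))
  if (n1 + n2 <= 12L) {
    ## exact conditional null: U over all choose(n1+n2, n1) group splits of
    ## the observed (possibly tied) ranks
    combs <- utils::combn(n1 + n2, n1)
    base <- n1 * (n1 + 1) / 2
    us <- colSums(matrix(r[combs], nrow = n1)) - base
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    return(.testResult(U, p, "mann-whitney exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (U - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  .testResult(U, min(1, p), "mann-whitney normal")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D statistic (max ECDF gap) with asymptotic p-value.
#'
#' @param x,y numeric samples.
#' @return A test-result list; `warning` flags samples smaller than 3.
#' @export
ksTest <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  warn <- if (length(x) < 3 || length(y) < 3) "small sample" else NA_character_
  sup <- sort(unique(c(x, y)))
  D <- max(abs(stats::ecdf(x)(sup) - stats::ecdf(y)(sup)))
  ne <- length(x) * length(y) / (length(x) + length(y))
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * lambda^2 * k^2))
  .testResult(D, min(1, max(0, p)), "kolmogorov-smirnov", warning = warn)
}

#' Chi-squared test on two error proportions
#'
#' 2x2 chi-squared without continuity correction on error counts versus
#' totals; expected cell counts are reported and small expected counts are
#' flagged.
#'
#' @param errors_a,n_a errors and total in group A.
#' @param errors_b,n_b errors and total in group B.
#' @return A test-result list with an `expected` matrix attached.
#' @export
proportionTest <- function(errors_a, n_a, errors_b, n_b) {
  stopifnot(errors_a <= n_a, errors_b <= n_b)
  O <- rbind(c(errors_a, n_a - errors_a), c(errors_b, n_b - errors_b))
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  if (any(cs == 0)) {
    out <- .testResult(0, 1, "chi-squared", degenerate = TRUE)
    out$expected <- O * NA
    return(out)
  }
  E <- outer(rs, cs) / N
  stat <- sum((O - E)^2 / E)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out <- .testResult(stat, p, "chi-squared",
                     warning = if (any(E < 1)) "low expected count"
                               else NA_character_)
  out$expected <- E
  out
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' @param groups named list of numeric samples (at least 2 groups of at
#'   least 2 values).
#' @return List with `anova` (test-result for the F test) and `pairwise`
#'   (list of test-results, `p_value` Bonferroni-adjusted as
#'   `min(1, m * p_raw)` with m the number of pairs; raw p in `p_raw`).
#' @export
anovaBonferroni <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, integer(1)) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  v <- unlist(groups, use.names = FALSE)
  f <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    an <- .testResult(0, 1, "anova", degenerate = TRUE)
  } else {
    fit <- stats::anova(stats::lm(v ~ f))
    an <- .testResult(fit[["F value"]][1], fit[["Pr(>F)"]][1], "anova")
  }
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  pw <- lapply(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    if (stats::var(c(a, b)) == 0) {
      res <- .testResult(0, 1, "t-test bonferroni", adjusted = TRUE,
                         degenerate = TRUE)
      res$p_raw <- 1
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      res <- .testResult(tt$statistic, min(1, m * tt$p.value),
                         "t-test bonferroni", adjusted = TRUE)
      res$p_raw <- tt$p.value
    }
    res$pair <- pr
    res
  })
  list(anova = an, pairwise = pw)
}

#' Percent change relative to a reference
#'
#' @param a value.
#' @param b positive reference value.
#' @return List with `percent` (100 * (a - b) / b) and `rounded`
#'   (nearest integer).
#' @export
percentChange <- function(a, b) {
  if (b <= 0) stop("reference value must be positive")
  pct <- 100 * (a - b) / b
  list(percent = pct, rounded = round(pct))
}

#' Cohort summary table
#'
#' One row per genotype: n, guidance-error frequency, and mean +/- SEM of
#' branch count, total arbor size and varicosity count (SEM = SD / sqrt(n)).
#'
#' @param cohorts named list; each element a per-arbor metrics data.frame as
#'   from [summarizeCohort()].
#' @return data.frame with one row per genotype, in input order; single-arbor
#'   cohorts get SEM 0 and `degenerate = TRUE`.
#' @export
cohortTable <- function(cohorts) {
  stopifnot(length(cohorts) > 0, all(vapply(cohorts, nrow, integer(1)) > 0))
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  rows <- lapply(names(cohorts), function(g) {
    m <- cohorts[[g]]
    data.frame(
      genotype = g, n = nrow(m),
      guidance_error_freq = mean(m$guidance_error),
      branch_mean = mean(m$branch_count), branch_sem = sem(m$branch_count),
      total_len_mean = mean(m$total_length),
      total_len_sem = sem(m$total_length),
      varicosity_mean = mean(m$varicosity_count),
      varicosity_sem = sem(m$varicosity_count),
      varicosities_per_branch = mean(m$varicosities_per_branch),
      degenerate = nrow(m) < 2,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative-frequency histogram of total arbor lengths
#'
#' Bins are `[k * bin, (k + 1) * bin)`; frequencies sum to 1.
#'
#' @param metrics per-arbor metrics data.frame (uses `total_length`).
#' @param bin_width bin width in micrometers (default 100).
#' @return data.frame with `bin_lo`, `bin_hi`, `frequency`.
#' @export
lengthHistogram <- function(metrics, bin_width = 100) {
  stopifnot(bin_width > 0)
  if (!nrow(metrics)) stop("empty cohort")
  k <- floor(metrics$total_length / bin_width)
  tab <- table(k)
  kk <- as.integer(names(tab))
  data.frame(bin_lo = kk * bin_width, bin_hi = (kk + 1) * bin_width,
             frequency = as.numeric(tab) / sum(tab))
}
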