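## Analytic calibration of a GenotypeConfig against a SkeletonTemplate.
##
## The generator has four free mean parameters (global length scale, skeletal
## presence scale, variable-branch rate, varicosity density) and three
## dispersion parameters (variable-count SD, per-animal arbor-size CV,
## per-animal varicosity-density CV).  Means are moment-matched so that the
## analytic expectations of branch count, total length and varicosity count
## (after the 4-um filter and size normalization) equal the configured
## targets; dispersions are matched to the configured cohort SEMs via the
## SD = SEM * sqrt(n) convention, clamped at the structural floor.

## generator constants (documented in the methods vignette)
.GEN <- list(
  var_len_mean = 25,        # base mean length of variable branches (um)
  var_len_cv   = 0.35,      # CV of variable-branch length
  dir_jitter   = 2.5 * pi / 180,  # SD of skeletal direction jitter (rad)
  routing_min  = 55 * pi / 180,   # routing-error deviation range (rad)
  routing_max  = 110 * pi / 180,
  min_sib_angle = 35 * pi / 180,  # min angle between segments at a junction
  hardcore     = 3,         # min varicosity spacing (um)
  max_rate     = 0.32,      # saturation of the varicosity rate (1/um)
  vari_diam    = c(mean = 3.4, sd = 0.4, min = 2.8, max = 4.6),  # um
  vari_gain    = c(mean = 2.6, sd = 0.3, min = 2.2, max = 3.6),
  h_cap        = 3.5,       # cap on the per-animal varicosity-density factor
  compensation = 0.6,       # variable growth recovers this fraction of the
                            # arbor's skeletal-length shortfall
  size_cv      = 0.05,      # animal-size factor (removed by normalization)
  size_range   = c(0.85, 1.15),
  entry_jitter = 2,         # SD of entry-point jitter (um)
  guidance_shift = 130,     # posterior displacement of a misrouted entry (um)
  filter_um    = 4          # countable-branch threshold (um, exclusive)
)

## expectation machinery ------------------------------------------------------

## per-branch keep probability and kept-length moments, marginalized over the
## mean-1 gamma size factor g (lengths g*T, kept iff g*T > cut)
.keepMoments <- function(m, s, cut, cvg) {
  if (cvg <= 0) {
    tm <- truncNormMoments(m, s, cut)
    return(list(P = tm$P, M1 = tm$M1, M2 = tm$M2))
  }
  P  <- gammaQuadrature(cvg, function(g) truncNormMoments(m, s, cut / g)$P)
  M1 <- gammaQuadrature(cvg, function(g) g * truncNormMoments(m, s, cut / g)$M1)
  M2 <- gammaQuadrature(cvg, function(g) g^2 * truncNormMoments(m, s, cut / g)$M2)
  list(P = P, M1 = M1, M2 = M2)
}

## marginal presence probabilities under the skeleton presence scale:
## obligate branches (presence 1) stay 1; others scale multiplicatively
.presenceMarginals <- function(template, kappa) {
  p <- template@branches$presence_prob
  ifelse(p >= 1 - 1e-12, 1, pmin(1, kappa * p))
}

## ancestor index list (template order, parents first)
.ancestorList <- function(parent_id, ids) {
  idx <- stats::setNames(seq_along(ids), ids)
  lapply(seq_along(ids), function(i) {
    anc <- integer(0)
    p <- parent_id[i]
    while (!is.na(p)) { j <- idx[[p]]; anc <- c(anc, j); p <- parent_id[j] }
    anc
  })
}

#' Analytic generator expectations
#'
#' Expected per-arbor branch count, total length, varicosity count and
#' skeletal count (after the 4-um filter, at the reference ganglion width)
#' implied by a configuration's generator parameters, plus approximate
#' per-arbor variances used for dispersion matching.
#'
#' @param config a [GenotypeConfig-class] (calibrated or not).
#' @param template a [SkeletonTemplate-class].
#' @return Named list with `branch_mean`, `total_len_mean`, `varicosity_mean`,
#'   `skeletal_mean`, `branch_var`, `total_len_var`, `varicosity_var` and
#'   `struct_len_var` (length variance before the common size factor).
#' @export
expectedMoments <- function(config, template) {
  b <- template@branches
  cut <- .GEN$filter_um
  s <- config@lengthScale
  cvg <- config@lengthDispCV
  cvh <- config@varicosityDispCV
  q <- .presenceMarginals(template, config@skeletonPresenceScale)
  lam <- config@variableBranchRate
  sK <- config@variableBranchSD
  rho <- config@varicosityDensity
  vm <- s * .GEN$var_len_mean
  vs <- vm * .GEN$var_len_cv

  ## means, marginalized over the size factor g
  mg <- lapply(seq_len(nrow(b)), function(i)
    .keepMoments(s * b$mean_length[i], s * b$sd_length[i], cut, cvg))
  Pg  <- vapply(mg, `[[`, numeric(1), "P")
  M1g <- vapply(mg, `[[`, numeric(1), "M1")
  kvg <- .keepMoments(vm, vs, cut, cvg)
  skel_mean <- sum(q * Pg)
  n_mean <- skel_mean + lam * kvg$P
  len_mean <- sum(q * M1g) + lam * kvg$M1
  vari_mean <- rho * len_mean

  ## variances, conditional on g = 1, inflated by the common factor afterwards
  m1 <- lapply(seq_len(nrow(b)), function(i)
    .keepMoments(s * b$mean_length[i], s * b$sd_length[i], cut, 0))
  P  <- vapply(m1, `[[`, numeric(1), "P")
  M1 <- vapply(m1, `[[`, numeric(1), "M1")
  M2 <- vapply(m1, `[[`, numeric(1), "M2")
  kv <- .keepMoments(vm, vs, cut, 0)
  anc <- .ancestorList(b$parent_id, b$id)
  covN <- 0; covL <- 0
  for (j in seq_along(anc)) for (i in anc[[j]]) {
    covN <- covN + P[i] * P[j] * q[j] * (1 - q[i])
    covL <- covL + M1[i] * M1[j] * q[j] * (1 - q[i])
  }
  kept_count_var <- kv$P^2 * (sK^2 + 1 / 12) + lam * kv$P * (1 - kv$P)
  n_var <- sum(q * P * (1 - q * P)) + 2 * covN + kept_count_var
  struct <- sum(q * M2 - (q * M1)^2) + 2 * covL
  if (kv$P > 0) {
    eY <- kv$M1 / kv$P
    vY <- max(0, kv$M2 / kv$P - eY^2)
    struct <- struct + lam * kv$P * vY + kept_count_var * eY^2
  }
  l_var <- (1 + cvg^2) * (struct + len_mean^2) - len_mean^2
  v_var <- vari_mean + rho^2 * ((1 + cvh^2) * (l_var + len_mean^2) - len_mean^2)
  list(branch_mean = n_mean, total_len_mean = len_mean,
       varicosity_mean = vari_mean, skeletal_mean = skel_mean,
       branch_var = n_var, total_len_var = l_var, varicosity_var = v_var,
       struct_len_var = struct)
}

#' Calibrate a genotype configuration against a template
#'
#' Deterministically moment-matches the free generator parameters so that the
#' analytic expectations of branch count, total arbor length and varicosity
#' count equal the configured targets, and the per-arbor dispersions
#' reproduce the configured cohort SEMs (SD = SEM * sqrt(n)) where
#' structurally reachable (dispersion knobs are clamped at zero when the
#' structural variance already exceeds the target).
#'
#' @param config an (uncalibrated) [GenotypeConfig-class].
#' @param template a [SkeletonTemplate-class].
#' @return The calibrated [GenotypeConfig-class].
#' @examples
#' cfg <- packagedGenotypes()[["w-"]]
#' cal <- calibrateConfig(cfg, wildtypeTemplate())
#' expectedMoments(cal, wildtypeTemplate())$branch_mean  # ~22.5
#' @export
calibrateConfig <- function(config, template) {
  t <- config@targets
  Bs <- t[["branch_mean"]]; Ls <- t[["total_len_mean"]]
  Vs <- t[["varicosity_mean"]]; Ss <- t[["skeletal_mean"]]
  n <- config@nAnimals
  b <- template@branches
  cut <- .GEN$filter_um
  p <- b$presence_prob
  oblig <- p >= 1 - 1e-12

  if (Bs < Ss)
    stop("infeasible targets: branch_mean below skeletal_mean ",
         "(binding constraint: expected skeletal count)")

  cvg <- 0
  for (iter in 1:3) {
    solveMeans <- function(s) {
      km <- lapply(seq_len(nrow(b)), function(i)
        .keepMoments(s * b$mean_length[i], s * b$sd_length[i], cut, cvg))
      P <- vapply(km, `[[`, numeric(1), "P")
      M1 <- vapply(km, `[[`, numeric(1), "M1")
      O <- sum(P[oblig])
      N <- sum((p * P)[!oblig])
      kappa <- (Ss - O) / N
      kv <- .keepMoments(s * .GEN$var_len_mean,
                         s * .GEN$var_len_mean * .GEN$var_len_cv, cut, cvg)
      lam <- (Bs - Ss) / kv$P
      q <- ifelse(oblig, 1, pmin(1, kappa * p))
      list(kappa = kappa, lam = lam, len = sum(q * M1) + lam * kv$M1)
    }
    s <- stats::uniroot(function(x) solveMeans(x)$len - Ls,
                        c(0.2, 4), tol = 1e-9)$root
    sol <- solveMeans(s)
    if (sol$kappa > 1 + 1e-6)
      stop("infeasible targets: skeletal_mean exceeds template capacity ",
           "(binding constraint: presence marginals at their ceiling)")
    if (sol$kappa < 0)
      stop("infeasible targets: skeletal_mean below the obligate-branch floor")
    config@lengthScale <- s
    config@skeletonPresenceScale <- sol$kappa
    config@variableBranchRate <- sol$lam
    config@varicosityDensity <- Vs / Ls

    ## dispersion matching at the current means
    config@variableBranchSD <- 0
    config@lengthDispCV <- 0
    config@varicosityDispCV <- 0
    mom0 <- expectedMoments(config, template)
    kv0 <- .keepMoments(s * .GEN$var_len_mean,
                        s * .GEN$var_len_mean * .GEN$var_len_cv, cut, 0)
    kvP <- kv0$P
    Vc <- (t[["branch_sem"]] * sqrt(n))^2
    VL <- (t[["total_len_sem"]] * sqrt(n))^2
    sdFromCount <- sqrt(max(0, (Vc - mom0$branch_var) / kvP^2))
    ## joint feasibility: count dispersion feeds total-length variance, so a
    ## count SD matched to a loose count SEM can overshoot a tight length
    ## SEM; the tighter (length) constraint binds
    eY <- kv0$M1 / kvP
    sdFromLength <- sqrt(max(0, (VL - mom0$struct_len_var) /
                                  (kvP^2 * eY^2)))
    config@variableBranchSD <- min(sdFromCount, sdFromLength)
    struct <- mom0$struct_len_var
    config@lengthDispCV <- sqrt(max(0, (VL + Ls^2) / (struct + Ls^2) - 1))
    VV <- (t[["varicosity_sem"]] * sqrt(n))^2
    lvar <- (1 + config@lengthDispCV^2) * (struct + Ls^2) - Ls^2
    rho <- config@varicosityDensity
    config@varicosityDispCV <-
      sqrt(max(0, (VV - Vs - rho^2 * lvar) / (rho^2 * (lvar + Ls^2))))
    cvg <- config@lengthDispCV
  }
  config@calibrated <- TRUE
  config
}

#' Check that a configuration's expectations meet its targets
#'
#' @param config a [GenotypeConfig-class].
#' @param template a [SkeletonTemplate-class].
#' @param tol relative tolerance (the generator refuses configurations off by
#'   more than 5%).
#' @return Invisibly `TRUE`; otherwise an error describing the discrepancy.
#' @export
checkCalibration <- function(config, template, tol = 0.05) {
  if (!config@calibrated)
    stop("configuration '", config@name, "' is not calibrated; ",
         "run calibrateConfig() first")
  mom <- expectedMoments(config, template)
  t <- config@targets
  for (k in c("branch_mean", "total_len_mean", "varicosity_mean")) {
    rel <- abs(mom[[k]] - t[[k]]) / t[[k]]
    if (is.na(rel) || rel > tol)
      stop(sprintf(
        "calibration error: expected %s = %.3f differs from target %.3f by %.1f%%",
        k, mom[[k]], t[[k]], 100 * rel))
  }
  invisible(TRUE)
}
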