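## Ground-truth arbor and cohort generation.
##
## An arbor is sampled branch by branch from the skeleton template:
## hierarchical presence (a branch can only be present when its parent is),
## truncated-normal lengths at the calibrated global scale, jittered
## directions with optional routing-error perturbations, variable branches
## attached at junction/tip nodes with directions kept clear of existing
## segments, and varicosities from a stationary hard-core renewal process.
## All geometry is kept inside the imaging field of view.

.inBox <- function(p, margin = .FOV_MARGIN) {
  p[1] >= margin && p[1] <= .FOV[1] - margin &&
    p[2] >= margin && p[2] <= .FOV[2] - margin
}

## meandering polyline of exact arc length `len` whose endpoint lies `chord`
## micrometers from `start` along `dir` (branch endpoints are stereotyped;
## length variation is expressed as path tortuosity). Where the path would
## leave the field it is bent at the offending vertex (the tail is rotated
## inward), so the arc length is preserved exactly.
.bowedPolyline <- function(start, dir, len, chord = NULL) {
  if (is.null(chord) || chord > len) chord <- len
  chord <- max(chord, 0.55 * len)     # cap tortuosity
  nseg <- max(8L, ceiling(len / 6))
  tt <- seq(0, 1, length.out = nseg + 1L)
  perp <- c(-dir[2], dir[1])
  sgn <- if (stats::runif(1) < 0.5) -1 else 1
  ## pick the meander frequency so the amplitude stays ~3 um: the length
  ## excess over the chord is spread over more periods on long branches
  kper <- max(3L, ceiling(chord * sqrt(max(len / chord - 1, 0.04)) / 4.7))
  shape <- sgn * sin(kper * pi * tt)
  base0 <- outer(tt * chord, dir)
  if (len > chord + 1e-9) {
    ## analytic amplitude guess + secant corrections; the final rescale
    ## makes the arc length exact
    arcOf <- function(a) polylineLength(base0 + outer(a * shape, perp))
    amp <- 2 * chord * sqrt(len / chord - 1) / (kper * pi)
    for (it in 1:3) {
      cur <- arcOf(amp)
      if (abs(cur - len) < 1e-3) break
      amp <- amp * sqrt(max(len - chord, 1e-9) / max(cur - chord, 1e-9))
    }
    base <- base0 + outer(amp * shape, perp)
  } else base <- base0
  arc <- polylineLength(base)
  p <- sweep(base * (len / arc), 2, start, "+")
  m <- .FOV_MARGIN
  inside <- function(v) v[1] >= m && v[1] <= .FOV[1] - m &&
    v[2] >= m && v[2] <= .FOV[2] - m
  for (i in 2:nrow(p)) {
    if (inside(p[i, ])) next
    pivot <- p[i - 1L, ]
    tail <- sweep(p[i:nrow(p), , drop = FALSE], 2, pivot)
    done <- FALSE
    for (adeg in c(15, -15, 30, -30, 45, -45, 60, -60, 90, -90, 120, -120,
                   150, -150, 180)) {
      a <- adeg * pi / 180
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
      cand <- tail %*% t(R)
      if (inside(cand[1, ] + pivot)) {
        p[i:nrow(p), ] <- sweep(cand, 2, pivot, "+")
        done <- TRUE
        break
      }
    }
    if (!done) {  # trapped (degenerate start on the margin): clamp
      p[i, 1] <- min(max(p[i, 1], m), .FOV[1] - m)
      p[i, 2] <- min(max(p[i, 2], m), .FOV[2] - m)
    }
  }
  p
}

## stationary hard-core renewal positions on [0, len] at rate `rate`
.renewalPositions <- function(len, rate) {
  h <- .GEN$hardcore
  rate <- min(rate, .GEN$max_rate)
  if (rate <= 0 || len <= 0) return(numeric(0))
  beta <- rate / (1 - rate * h)
  x <- if (stats::runif(1) < rate * h) stats::runif(1, 0, h)
       else h + stats::rexp(1, beta)
  out <- numeric(0)
  while (x <= len) {
    out <- c(out, x)
    x <- x + h + stats::rexp(1, beta)
  }
  out
}

## move positions out of exclusion zones (junction neighborhoods); the shift
## preserves the expected count
.shiftPositions <- function(pos, len, zones) {
  if (!length(pos) || is.null(zones) || !nrow(zones)) return(pos)
  for (pass in 1:2) {
    for (z in seq_len(nrow(zones))) {
      lo <- zones[z, 1]; hi <- zones[z, 2]
      inside <- pos > lo & pos < hi
      if (!any(inside)) next
      mid <- (lo + hi) / 2
      pos[inside] <- ifelse(pos[inside] <= mid,
                            max(lo, 0.2), min(hi, len - 0.2))
    }
  }
  pos[pos >= 0 & pos <= len]
}

## varicosity marks for one branch
.sampleVaricosities <- function(len, rate, zones = NULL) {
  pos <- .renewalPositions(len, rate)
  pos <- .shiftPositions(pos, len, zones)
  if (!length(pos))
    return(data.frame(arc_position = numeric(0), diameter = numeric(0),
                      intensity_gain = numeric(0)))
  d <- .GEN$vari_diam; g <- .GEN$vari_gain
  structure(list(
    arc_position = pos,
    diameter = pmax(d[["min"]], pmin(d[["max"]],
                    stats::rnorm(length(pos), d[["mean"]], d[["sd"]]))),
    intensity_gain = pmax(g[["min"]], pmin(g[["max"]],
                    stats::rnorm(length(pos), g[["mean"]], g[["sd"]])))),
    class = "data.frame", row.names = seq_along(pos))
}

#' Sample one ground-truth arbor
#'
#' Draws a single arbor from a calibrated genotype configuration using the
#' current RNG state (seed the stream, or use [sampleCohort()], for
#' reproducibility).
#'
#' @param config a calibrated [GenotypeConfig-class].
#' @param template a [SkeletonTemplate-class].
#' @param check verify the calibration before sampling (refuses
#'   configurations whose expected totals are off by more than 5%).
#' @return An [ArborTree-class] with ground-truth labels, routing flags and
#'   varicosities.
#' @export
sampleArbor <- function(config, template, check = TRUE) {
  if (check) checkCalibration(config, template)
  b <- template@branches
  s <- config@lengthScale
  q <- .presenceMarginals(template, config@skeletonPresenceScale)
  idx <- stats::setNames(seq_len(nrow(b)), b$id)

  fsz <- 0
  while (fsz < .GEN$size_range[1] || fsz > .GEN$size_range[2])
    fsz <- stats::rnorm(1, 1, .GEN$size_cv)
  g <- rGammaCV(1, config@lengthDispCV)
  ## per-animal varicosity-density factor, capped: densities beyond a few
  ## times the cohort mean collide with the hard-core spacing and stop being
  ## countable; the closed-form renormalization keeps the mean exactly 1
  h <- rGammaCV(1, config@varicosityDispCV)
  cvh <- config@varicosityDispCV
  if (cvh > 0) {
    a <- 1 / cvh^2
    cap <- .GEN$h_cap
    emin <- stats::pgamma(cap, a + 1, a) +
      cap * stats::pgamma(cap, a, a, lower.tail = FALSE)
    h <- min(h, cap) / emin
  }
  guidance <- stats::runif(1) < config@guidanceErrorRate
  entry <- .ENTRY + stats::rnorm(2, 0, .GEN$entry_jitter)

  ## hierarchical presence: conditional = ratio of marginals
  present <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    pid <- b$parent_id[i]
    if (is.na(pid)) present[i] <- stats::runif(1) < q[i]
    else if (!present[idx[[pid]]]) { stats::runif(1); present[i] <- FALSE }
    else present[i] <- stats::runif(1) < min(1, q[i] / q[idx[[pid]]])
  }

  branchesOut <- list()
  ends <- list()        # branch id -> end vertex
  nodeDirs <- list()    # node key -> matrix of unit directions leaving it
  rate <- min(h * config@varicosityDensity, .GEN$max_rate)

  ## occupancy grid (2 um cells, ~4 um dilation) for fast clearance queries
  cell <- 2
  gnx <- ceiling(.FOV[1] / cell) + 4L
  gny <- ceiling(.FOV[2] / cell) + 4L
  occ <- matrix(FALSE, gnx, gny)
  markOcc <- function(poly) {
    ## polyline vertices are ~4-5 um apart; with the +-2 cell dilation this
    ## covers the cable without resampling
    ci <- pmin(pmax(as.integer(poly[, 1] / cell) + 2L, 3L), gnx - 2L)
    cj <- pmin(pmax(as.integer(poly[, 2] / cell) + 2L, 3L), gny - 2L)
    lin <- integer(0)
    for (di in -2:2) for (dj in -2:2)
      lin <- c(lin, (cj + dj - 1L) * gnx + ci + di)
    occ[lin] <<- TRUE
  }
  clearAlong <- function(start, dir, len) {
    at <- seq.int(8, max(len, 8.5), by = cell)
    ci <- pmin(pmax(floor((start[1] + dir[1] * at) / cell) + 2L, 3L), gnx - 2L)
    cj <- pmin(pmax(floor((start[2] + dir[2] * at) / cell) + 2L, 3L), gny - 2L)
    !any(occ[cbind(ci, cj)])
  }

  addNodeDir <- function(key, dir) {
    nodeDirs[[key]] <<- rbind(nodeDirs[[key]], dir)
  }
  nodeKey <- function(p) sprintf("%.3f_%.3f", p[1], p[2])

  for (i in seq_len(nrow(b))) {
    if (!present[i]) next
    pid <- b$parent_id[i]
    start <- if (is.na(pid)) entry else ends[[pid]]
    dir0 <- unitVec(c(b$dir_x[i], b$dir_y[i]))
    routed <- !is.na(pid) && stats::runif(1) < config@routingErrorRate
    if (routed) {
      ang <- sample(c(-1, 1), 1) * stats::runif(1, .GEN$routing_min,
                                                .GEN$routing_max)
      dir0 <- rotate2(dir0, ang)
    }
    len <- g * rTruncNorm0(1, s * b$mean_length[i], s * b$sd_length[i])
    dir <- rotate2(dir0, stats::rnorm(1, 0, .GEN$dir_jitter))
    poly <- .bowedPolyline(start, dir, len,
                           chord = 0.9 * g * s * b$mean_length[i])
    br <- .newBranch(b$id[i], if (is.na(pid)) NA_character_ else pid, poly,
                     label = paste0("skeletal:", b$id[i]),
                     routingError = routed)
    branchesOut[[b$id[i]]] <- br
    ends[[b$id[i]]] <- poly[nrow(poly), ]
    addNodeDir(nodeKey(start), dir)
    addNodeDir(nodeKey(ends[[b$id[i]]]), -dir)
    markOcc(poly)
  }

  ## variable branches: calibrated-dispersion count, attached interstitially
  ## (mid-branch, like real collateral sprouts), growing into free neuropil.
  ## Variable growth partly compensates the arbor's skeletal-length
  ## shortfall (the printed count and length dispersions jointly imply this
  ## anticorrelation); the coupling is mean-preserving.
  nvar <- max(0L, as.integer(round(stats::rnorm(1, config@variableBranchRate,
                                                config@variableBranchSD))))
  vm <- s * .GEN$var_len_mean
  expSkel <- g * sum(q * s * b$mean_length)
  actSkel <- sum(vapply(branchesOut, function(br) br@length, numeric(1)))
  budget <- config@variableBranchRate * vm * g
  if (budget > 1) {
    mult <- max(0.3, 1 + .GEN$compensation * (expSkel - actSkel) / budget)
    vm <- vm * mult
  }
  vs <- vm * .GEN$var_len_cv
  attachArcs <- list()   # host id -> arc positions already used
  arcCache <- list()     # host id -> cumulative arc lengths of its polyline
  atArc <- function(host, t) {
    cc <- arcCache[[host]]
    if (is.null(cc)) {
      pp <- branchesOut[[host]]@polyline
      cc <- list(p = pp, s = c(0, cumsum(sqrt(rowSums(diff(pp)^2)))))
      arcCache[[host]] <<- cc
    }
    t <- max(0, min(t, cc$s[length(cc$s)]))
    i <- findInterval(t, cc$s, rightmost.closed = TRUE)
    i <- max(1L, min(i, nrow(cc$p) - 1L))
    seg <- cc$s[i + 1L] - cc$s[i]
    f <- if (seg > 0) (t - cc$s[i]) / seg else 0
    cc$p[i, ] + f * (cc$p[i + 1L, ] - cc$p[i, ])
  }
  for (k in seq_len(nvar)) {
    hosts <- names(branchesOut)
    hlen <- vapply(branchesOut, function(b) b@length, numeric(1))
    w <- pmax(hlen - 10, 0)
    if (!length(hosts) || sum(w) <= 0) break
    len <- g * rTruncNorm0(1, vm, vs)
    best <- NULL; bestScore <- -Inf
    for (try in 1:25) {
      host <- hosts[sample.int(length(hosts), 1, prob = w)]
      hL <- branchesOut[[host]]@length
      u <- stats::runif(1, 5, hL - 5)
      th <- stats::runif(1, 0, 2 * pi)
      ## keep attachments separated along the host
      if (any(abs(attachArcs[[host]] - u) < 4)) next
      start <- atArc(host, u)
      dir <- c(cos(th), sin(th))
      fits <- .inBox(start + dir * len)
      clear <- clearAlong(start, dir, len)
      score <- (if (clear) 5 else 0) + (if (fits) 10 else 0) +
        stats::runif(1, 0, 0.1)
      okAngle <- FALSE
      if (clear && fits) {
        tangent <- unitVec(atArc(host, min(u + 2, hL)) -
                           atArc(host, max(u - 2, 0)))
        tang_ang <- angleBetween(tangent, dir)
        okAngle <- tang_ang > .GEN$min_sib_angle &&
          tang_ang < pi - .GEN$min_sib_angle
        if (!okAngle) score <- score - 3
      }
      if (score > bestScore) {
        bestScore <- score
        best <- list(host = host, start = start, dir = dir, u = u)
      }
      if (fits && okAngle && clear) break
    }
    if (is.null(best)) next
    id <- sprintf("v%02d", k)
    poly <- .bowedPolyline(best$start, best$dir, len, chord = 0.92 * len)
    br <- .newBranch(id, best$host, poly, label = "variable")
    branchesOut[[id]] <- br
    ends[[id]] <- poly[nrow(poly), ]
    attachArcs[[best$host]] <- c(attachArcs[[best$host]], best$u)
    markOcc(poly)
  }

  ## varicosities: renewal placement per branch, kept clear of junction
  ## neighborhoods (boutons and branch points are distinct structures)
  endHosts <- unique(stats::na.omit(vapply(branchesOut, function(b)
    if (startsWith(b@label, "skeletal") && !is.na(b@parentId)) b@parentId
    else NA_character_, character(1))))
  for (id in names(branchesOut)) {
    br <- branchesOut[[id]]
    L <- br@length
    zones <- rbind(c(0, 2.5))
    if (id %in% endHosts) zones <- rbind(zones, c(L - 2.5, L))
    for (u in attachArcs[[id]]) zones <- rbind(zones, c(u - 2.5, u + 2.5))
    br@varicosities <- .sampleVaricosities(L, rate, zones)
    branchesOut[[id]] <- br
  }

  ## animal-size factor: scales all coordinates and the ganglion width
  rootStart <- if (length(branchesOut)) branchesOut[[1]]@polyline[1, ] else entry
  branchesOut <- lapply(branchesOut, function(br) {
    br@polyline <- br@polyline * fsz
    br@length <- br@length * fsz
    br@varicosities$arc_position <- br@varicosities$arc_position * fsz
    br
  })
  entryPoint <- rootStart * fsz
  if (guidance) entryPoint <- entryPoint + c(0, .GEN$guidance_shift) * fsz

  .newArborTree(entryPoint = entryPoint,
                entryRegion = if (guidance) "metathoracic" else "mesothoracic",
                ganglionWidth = .FOV[1] * fsz,
                branches = unname(branchesOut), genotype = config@name,
                guidanceError = guidance)
}

#' Sample a cohort of arbors
#'
#' @param config a calibrated [GenotypeConfig-class].
#' @param template a [SkeletonTemplate-class].
#' @param seed integer seed (defaults to the configuration's seed); given the
#'   same inputs the cohort is reproducible bit for bit.
#' @param n cohort size (defaults to the configuration's `n_animals`).
#' @return List of `n` [ArborTree-class] objects.
#' @export
sampleCohort <- function(config, template, seed = config@seed,
                         n = config@nAnimals) {
  checkCalibration(config, template)
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) sampleArbor(config, template, check = FALSE))
}
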