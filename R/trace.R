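## Tracing: recover an ArborTree and its varicosities from a rendered stack.
##
## Maximum projection -> threshold (Otsu by default) -> largest connected
## component -> Zhang-Suen centerlines -> segment graph (endpoints/junction
## clusters as nodes) -> cycle breaking at lowest-intensity segments ->
## pass-through fusing at 4-way crossings -> rooting at the node nearest the
## entry hint -> branches (spur-pruned, smoothed, micrometer-calibrated).

#' Tracing parameters
#'
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity threshold when `threshold_method` is
#'   `"fixed"`.
#' @param min_component_px connected components smaller than this are
#'   discarded before picking the largest.
#' @param prune_spur_um centerline spurs shorter than this are removed (must
#'   stay below 4 um so countable branches are never eaten).
#' @param varicosity_width_factor local width must exceed this multiple of
#'   the median branch width.
#' @param varicosity_intensity_factor local peak intensity must exceed this
#'   multiple of the median on-axon intensity.
#' @param min_varicosity_separation_um closer maxima are merged.
#' @return Named list of parameters.
#' @export
traceParams <- function(threshold_method = c("otsu", "fixed"),
                        fixed_threshold = 0.2, min_component_px = 30,
                        prune_spur_um = 2.5, varicosity_width_factor = 1.5,
                        varicosity_intensity_factor = 1.5,
                        min_varicosity_separation_um = 2.5) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(varicosity_width_factor > 1, varicosity_intensity_factor > 1,
            prune_spur_um < 4)
  list(threshold_method = threshold_method,
       fixed_threshold = fixed_threshold,
       min_component_px = min_component_px, prune_spur_um = prune_spur_um,
       varicosity_width_factor = varicosity_width_factor,
       varicosity_intensity_factor = varicosity_intensity_factor,
       min_varicosity_separation_um = min_varicosity_separation_um)
}

#' Project a stack and segment the axon
#'
#' @param stack a single-channel [ImageStack-class].
#' @param params from [traceParams()].
#' @return List with `projection` (matrix, per-pixel max over z), `mask`
#'   (logical matrix: largest connected foreground component) and
#'   `threshold`.
#' @export
projectAndSegment <- function(stack, params = traceParams()) {
  if (dim(stack@voxels)[4] != 1L) stop("expected a single-channel stack")
  proj <- maxProjection(stack, 1L)
  thr <- if (params$threshold_method == "otsu") {
    EBImage::otsu(EBImage::Image(pmin(pmax(proj, 0), 1)), range = c(0, 1))
  } else params$fixed_threshold
  fg <- proj > thr
  if (!any(fg) || mean(fg) > 0.5)
    stop("no axon found: empty foreground after thresholding")
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  sizes[sizes < params$min_component_px] <- 0L
  if (!any(sizes > 0)) stop("no axon found: all components below size floor")
  mask <- lab == which.max(sizes)
  list(projection = proj, mask = mask, threshold = thr)
}

## ---------------------------------------------------------------------------
## segment graph machinery (internal)

## cluster adjacent node pixels; returns cluster id per node pixel row
.clusterPixels <- function(pix) {
  n <- nrow(pix)
  if (n == 0L) return(integer(0))
  id <- integer(n)
  key <- stats::setNames(seq_len(n), paste(pix[, 1], pix[, 2]))
  cur <- 0L
  for (i in seq_len(n)) {
    if (id[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    id[i] <- cur
    while (length(queue)) {
      k <- queue[[1]]; queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        j <- key[paste(pix[k, 1] + dx, pix[k, 2] + dy)]
        if (!is.na(j) && id[j] == 0L) { id[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  id
}

## build the segment graph of a skeleton: nodes (junction clusters and
## endpoints) and segments (pixel chains between nodes)
.segmentGraph <- function(skel, proj) {
  deg <- .reducedDegree(skel)
  ## junction pixels (reduced degree >= 3) dilated by 2 px within the
  ## skeleton form node regions: thinning artifacts around junctions (pixel
  ## clusters, parallel stubs) are absorbed into a single graph node instead
  ## of spawning tiny segments
  junc <- skel & (deg >= 3L)
  ends <- skel & (deg <= 1L)
  if (any(junc)) {
    kern <- EBImage::makeBrush(5, "box")
    jreg <- EBImage::imageData(EBImage::dilate(EBImage::Image(junc * 1),
                                               kern)) > 0
    nodeMask <- skel & (jreg | ends)
  } else nodeMask <- skel & ends
  ## a pure cycle has no nodes; seed one artificial node on it
  if (!any(nodeMask) && any(skel)) {
    first <- which(skel, arr.ind = TRUE)[1, , drop = FALSE]
    nodeMask[first] <- TRUE
  }
  npix <- which(nodeMask, arr.ind = TRUE)
  cl <- .clusterPixels(npix)
  nodeOf <- new.env(hash = TRUE)
  for (i in seq_len(nrow(npix)))
    assign(paste(npix[i, 1], npix[i, 2]), cl[i], envir = nodeOf)
  ## node centers: mean over the core (junction/endpoint) pixels of the
  ## region, not the dilation halo, to keep branch splits accurate
  core <- junc[npix] | (skel & deg <= 1L)[npix]
  centers <- t(vapply(seq_len(max(cl, 0)), function(k) {
    sel <- cl == k & core
    if (!any(sel)) sel <- cl == k
    colMeans(npix[sel, , drop = FALSE])
  }, numeric(2)))

  isSkel <- function(x, y) x >= 1 && y >= 1 && x <= nrow(skel) &&
    y <= ncol(skel) && skel[x, y]
  nodeId <- function(x, y) {
    v <- mget(paste(x, y), envir = nodeOf, ifnotfound = list(NA_integer_))[[1]]
    v
  }
  visited <- matrix(FALSE, nrow(skel), ncol(skel))
  segs <- list()
  addSeg <- function(a, b, path) {
    segs[[length(segs) + 1L]] <<- list(
      from = a, to = b, path = path,
      intensity = mean(proj[path]),
      len_px = if (nrow(path) >= 2)
        sum(sqrt(rowSums(diff(path)^2))) else 0)
  }
  ## reduced adjacency: skip diagonal steps that shortcut two orthogonal ones
  neighborsOf <- function(x, y) {
    out <- NULL
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      if (!isSkel(x + dx, y + dy)) next
      if (dx != 0 && dy != 0 &&
          (isSkel(x + dx, y) || isSkel(x, y + dy))) next
      out <- rbind(out, c(x + dx, y + dy))
    }
    out
  }
  for (i in seq_len(nrow(npix))) {
    x0 <- npix[i, 1]; y0 <- npix[i, 2]
    a <- cl[i]
    nb <- neighborsOf(x0, y0)
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      nx <- nb[k, 1]; ny <- nb[k, 2]
      bnode <- nodeId(nx, ny)
      if (!is.na(bnode)) {
        ## directly adjacent node clusters
        if (bnode != a && a < bnode)
          addSeg(a, bnode, rbind(c(x0, y0), c(nx, ny)))
        next
      }
      if (visited[nx, ny]) next
      ## walk the chain
      path <- rbind(c(x0, y0), c(nx, ny))
      visited[nx, ny] <- TRUE
      px <- x0; py <- y0; cx <- nx; cy <- ny
      repeat {
        nn <- neighborsOf(cx, cy)
        nn <- nn[!(nn[, 1] == px & nn[, 2] == py), , drop = FALSE]
        ## prefer non-visited chain pixels / any node pixel
        if (nrow(nn) == 0L) { addSeg(a, NA_integer_, path); break }
        nodeHit <- which(!is.na(vapply(seq_len(nrow(nn)), function(q)
          nodeId(nn[q, 1], nn[q, 2]), integer(1))))
        if (length(nodeHit)) {
          q <- nodeHit[1]
          path <- rbind(path, nn[q, ])
          addSeg(a, nodeId(nn[q, 1], nn[q, 2]), path)
          break
        }
        free <- which(!visited[nn])
        if (!length(free)) { addSeg(a, NA_integer_, path); break }
        q <- free[1]
        px <- cx; py <- cy
        cx <- nn[q, 1]; cy <- nn[q, 2]
        visited[cx, cy] <- TRUE
        path <- rbind(path, c(cx, cy))
      }
    }
  }
  list(nodes = centers, segments = segs)
}

## break centerline cycles: segments are admitted in decreasing intensity
## order; a segment that would close a cycle is detached at one end (the
## higher-degree node) and keeps its geometry as a new tip, so no real
## branch material is deleted
.breakCycles <- function(nNodes, segs, nodes) {
  parent <- seq_len(nNodes + length(segs))
  find <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  degr <- integer(nNodes)
  for (s in segs) {
    if (is.na(s$to)) next
    degr[s$from] <- degr[s$from] + 1L
    degr[s$to] <- degr[s$to] + 1L
  }
  keep <- logical(length(segs))
  broke <- FALSE
  nextNode <- nNodes
  ord <- order(-vapply(segs, `[[`, numeric(1), "intensity"))
  for (i in ord) {
    s <- segs[[i]]
    if (is.na(s$to)) next               # degenerate dangling chain: drop
    a <- find(s$from); b <- find(s$to)
    if (a == b) {
      broke <- TRUE
      ## short cycle edges are junction artifacts: drop them; substantial
      ## ones are real branch material: detach at the busier node so the
      ## segment survives as a tip branch
      if (s$len_px < 24) next
      nextNode <- nextNode + 1L
      if (degr[s$from] >= degr[s$to]) {
        nodes <- rbind(nodes, nodes[s$from, ])
        s$from <- nextNode
      } else {
        nodes <- rbind(nodes, nodes[s$to, ])
        s$to <- nextNode
      }
      segs[[i]] <- s
    }
    a <- find(s$from); b <- find(s$to)
    if (a != b) parent[a] <- b
    keep[i] <- TRUE
  }
  list(segs = segs[keep], nodes = nodes, broke = broke,
       nNodes = nrow(nodes))
}

## number of connected components among nodes that carry segments
.nComponents <- function(segs, nNodes) {
  par <- seq_len(nNodes)
  find <- function(x) {
    while (par[x] != x) { par[x] <<- par[par[x]]; x <- par[x] }
    x
  }
  used <- integer(0)
  for (s in segs) {
    if (is.na(s$to)) next
    a <- find(s$from); b <- find(s$to)
    if (a != b) par[a] <- b
    used <- c(used, s$from, s$to)
  }
  used <- unique(used)
  length(unique(vapply(used, find, integer(1))))
}

## join two segments incident at node v into one pass-through segment
.joinAt <- function(si, sj, v) {
  pi_ <- si$path
  if (!is.na(si$to) && si$to == v) {
    afrom <- si$from
  } else {
    afrom <- si$to
    pi_ <- pi_[rev(seq_len(nrow(pi_))), , drop = FALSE]
  }
  pj <- sj$path
  if (sj$from == v) {
    bto <- sj$to
  } else {
    bto <- sj$from
    pj <- pj[rev(seq_len(nrow(pj))), , drop = FALSE]
  }
  list(from = afrom, to = bto, path = rbind(pi_, pj[-1, , drop = FALSE]),
       intensity = mean(c(si$intensity, sj$intensity)),
       len_px = si$len_px + sj$len_px)
}

## leaving-direction of segment i at node v (first ~6 px)
.segDirAt <- function(s, v) {
  p <- s$path
  if (!is.na(s$to) && s$to == v) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  k <- min(nrow(p), 7L)
  unitVec(p[k, ] - p[1, ])
}

## fuse pass-through pairs at 4-way crossing nodes; a fuse is accepted only
## if it does not disconnect the graph (true crossings sit on a cycle, real
## junctions do not)
.fuseCrossings <- function(segs, nNodes) {
  thr4 <- 150 * pi / 180
  repeat {
    inc <- vector("list", nNodes)
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      inc[[s$from]] <- c(inc[[s$from]], i)
      if (!is.na(s$to)) inc[[s$to]] <- c(inc[[s$to]], i)
    }
    fused <- FALSE
    for (v in seq_len(nNodes)) {
      ids <- inc[[v]]
      if (length(ids) != 4L || anyDuplicated(ids)) next
      dirs <- t(vapply(ids, function(i) .segDirAt(segs[[i]], v), numeric(2)))
      ang <- function(i, j) angleBetween(dirs[i, ], dirs[j, ])
      pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
      best <- NULL
      for (pp in pairings) {
        if (ang(pp[1], pp[2]) > thr4 && ang(pp[3], pp[4]) > thr4) {
          best <- pp; break
        }
      }
      if (is.null(best)) next
      s1 <- .joinAt(segs[[ids[best[1]]]], segs[[ids[best[2]]]], v)
      s2 <- .joinAt(segs[[ids[best[3]]]], segs[[ids[best[4]]]], v)
      if (is.na(s1$from) || is.na(s1$to) || is.na(s2$from) || is.na(s2$to))
        next
      if (s1$from == s1$to || s2$from == s2$to) next
      cand <- c(segs[-ids], list(s1, s2))
      if (.nComponents(cand, nNodes) > .nComponents(segs, nNodes)) next
      segs <- cand
      fused <- TRUE
      break
    }
    if (!fused) break
  }
  segs
}

## moving-average smoothing of a polyline (endpoints fixed)
.smoothPolyline <- function(p, window = 3L) {
  n <- nrow(p)
  if (n <= window) return(p)
  h <- window %/% 2L
  sm <- p
  for (i in seq(2L, n - 1L)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    sm[i, ] <- colMeans(p[lo:hi, , drop = FALSE])
  }
  sm
}

#' Extract a rooted arbor from a segmented projection
#'
#' @param mask logical axon mask (from [projectAndSegment()]).
#' @param projection intensity projection matrix.
#' @param entry_hint (x, y) in micrometers (image frame); the root is the
#'   graph node nearest this point.
#' @param params from [traceParams()].
#' @param pixel_size micrometers per pixel.
#' @param origin (x, y) of pixel (1, 1), micrometers.
#' @return An [ArborTree-class]; `@cyclesBroken` is `TRUE` when centerline
#'   cycles had to be broken at their lowest-intensity segment.
#' @export
extractTree <- function(mask, projection, entry_hint,
                        params = traceParams(), pixel_size = 0.5,
                        origin = c(0, 0)) {
  skel <- skeletonize(mask)
  g <- .segmentGraph(skel, projection)
  if (!length(g$segments)) stop("no centerline segments found")
  nNodes <- nrow(g$nodes)
  ## fuse pass-through pairs at 4-way crossings first: a crossing of two
  ## strands is then two independent segments and its cycle dissolves
  segs <- .fuseCrossings(g$segments, nNodes)
  bc <- .breakCycles(nNodes, segs, g$nodes)
  segs <- bc$segs
  g$nodes <- bc$nodes
  nNodes <- bc$nNodes

  ## contract tiny internal (junction-to-junction) segments: thinning
  ## artifacts around junctions must not become countable branches or split
  ## real ones
  repeat {
    degr <- integer(nNodes)
    for (s in segs) {
      degr[s$from] <- degr[s$from] + 1L
      degr[s$to] <- degr[s$to] + 1L
    }
    short <- which(vapply(segs, function(s)
      s$len_px * pixel_size < params$prune_spur_um &&
        degr[s$from] >= 2L && degr[s$to] >= 2L && s$from != s$to,
      logical(1)))
    if (!length(short)) break
    s <- segs[[short[1]]]
    keepN <- s$from; dropN <- s$to
    g$nodes[keepN, ] <- (g$nodes[keepN, ] + g$nodes[dropN, ]) / 2
    segs <- segs[-short[1]]
    segs <- lapply(segs, function(x) {
      if (!is.na(x$from) && x$from == dropN) x$from <- keepN
      if (!is.na(x$to) && x$to == dropN) x$to <- keepN
      x
    })
    ## contraction can create parallel duplicates or self loops; drop them
    sig <- vapply(segs, function(x) paste(sort(c(x$from, x$to)),
                                          collapse = "-"), character(1))
    self <- vapply(segs, function(x) x$from == x$to, logical(1))
    segs <- segs[!self & !duplicated(sig)]
  }

  toUm <- function(p) sweep((p - 1) * pixel_size, 2, origin, "+")
  nodeUm <- toUm(g$nodes)
  hintPx <- rbind(entry_hint)
  d2 <- (nodeUm[, 1] - entry_hint[1])^2 + (nodeUm[, 2] - entry_hint[2])^2
  ## root at the endpoint (degree-1) node nearest the hint: the axon enters
  ## at a tip, and an endpoint root keeps the branch decomposition a tree
  used <- sort(unique(unlist(lapply(segs, function(s) c(s$from, s$to)))))
  used <- used[!is.na(used)]
  degr <- integer(nNodes)
  for (s in segs) {
    degr[s$from] <- degr[s$from] + 1L
    degr[s$to] <- degr[s$to] + 1L
  }
  tips <- used[degr[used] == 1L]
  root <- if (length(tips)) tips[which.min(d2[tips])]
          else used[which.min(d2[used])]

  ## BFS over segments
  adj <- vector("list", nNodes)
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    adj[[s$from]] <- c(adj[[s$from]], i)
    adj[[s$to]] <- c(adj[[s$to]], i)
  }
  branchesOut <- list()
  nid <- 0L
  segUsed <- logical(length(segs))
  queue <- list(list(node = root, branch = NA_character_,
                     vertex = g$nodes[root, ]))
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (i in adj[[cur$node]]) {
      if (segUsed[i]) next
      segUsed[i] <- TRUE
      s <- segs[[i]]
      other <- if (s$from == cur$node) s$to else s$from
      p <- s$path
      if (s$from != cur$node) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      poly <- rbind(cur$vertex, p, g$nodes[other, ])
      nid <- nid + 1L
      id <- sprintf("t%03d", nid)
      branchesOut[[id]] <- list(id = id, parent = cur$branch, path = poly,
                                endNode = other)
      queue <- c(queue, list(list(node = other, branch = id,
                                  vertex = g$nodes[other, ])))
    }
  }

  ## spur pruning, pass-through merging and continuation merging on the
  ## raw px paths
  segDir <- function(path, from_end) {
    n <- nrow(path)
    k <- min(n, 15L)
    if (from_end) unitVec(path[n, ] - path[n - k + 1L, ])
    else unitVec(path[k, ] - path[1, ])
  }
  cont_thr <- 20 * pi / 180
  repeat {
    ids <- names(branchesOut)
    parents <- vapply(branchesOut, function(b) b$parent, character(1))
    hasKids <- ids %in% parents
    lens <- vapply(branchesOut, function(b)
      sum(sqrt(rowSums(diff(b$path)^2))) * pixel_size, numeric(1))
    drop <- !hasKids & lens < params$prune_spur_um
    if (any(drop)) { branchesOut <- branchesOut[!drop]; next }
    ## crossing remnants: a short leaf whose free tip dives into another
    ## strand is detached material from a broken crossing, not a protrusion
    stub <- FALSE
    for (id in ids[!hasKids & lens < 10 / pixel_size * pixel_size]) {
      if (lens[[id]] >= 10) next
      tip <- branchesOut[[id]]$path[nrow(branchesOut[[id]]$path), ]
      for (oid in ids) {
        if (oid == id) next
        op <- branchesOut[[oid]]$path
        dmin <- min(sqrt((op[, 1] - tip[1])^2 + (op[, 2] - tip[2])^2))
        if (dmin * pixel_size < 2.5) { stub <- TRUE; break }
      }
      if (stub) { branchesOut[[id]] <- NULL; break }
    }
    if (stub) next
    merged <- FALSE
    for (id in ids) {
      b <- branchesOut[[id]]
      kids <- ids[!is.na(parents) & parents == id]
      if (!length(kids)) next
      pend <- b$path[nrow(b$path), ]
      atEnd <- vapply(kids, function(k) {
        sqrt(sum((branchesOut[[k]]$path[1, ] - pend)^2)) <= 3
      }, logical(1))
      endKids <- kids[atEnd]
      if (!length(endKids)) next
      pick <- NULL
      if (length(endKids) == 1L) {
        ## degree-2 node: plain pass-through
        pick <- endKids
      } else {
        ## a child continuing the parent almost straight is the same
        ## protrusion; its siblings become interstitial children
        pdir <- segDir(b$path, TRUE)
        angs <- vapply(endKids, function(k)
          angleBetween(pdir, segDir(branchesOut[[k]]$path, FALSE)), numeric(1))
        straight <- which(angs < cont_thr)
        if (length(straight) == 1L) pick <- endKids[straight]
      }
      if (is.null(pick)) next
      cb <- branchesOut[[pick]]
      b$path <- rbind(b$path, cb$path[-1, , drop = FALSE])
      branchesOut[[id]] <- b
      for (j in ids) {
        if (j %in% names(branchesOut) &&
            identical(branchesOut[[j]]$parent, pick))
          branchesOut[[j]]$parent <- id
      }
      branchesOut[[pick]] <- NULL
      merged <- TRUE
      break
    }
    if (merged) next
    ## contract internal branches below the countable threshold (4 um):
    ## their children reattach to the grandparent (or, at the root, the
    ## first child is promoted), so downstream filtering cannot orphan a
    ## whole subtree behind a stub
    contracted <- FALSE
    for (id in ids) {
      if (!(id %in% names(branchesOut))) next
      if (lens[[id]] >= 4 || !hasKids[[match(id, ids)]]) next
      b <- branchesOut[[id]]
      kids <- ids[!is.na(parents) & parents == id]
      kids <- kids[kids %in% names(branchesOut)]
      if (is.na(b$parent)) {
        newRoot <- kids[1]
        branchesOut[[newRoot]]$parent <- NA_character_
        for (j in kids[-1]) branchesOut[[j]]$parent <- newRoot
      } else {
        for (j in kids) branchesOut[[j]]$parent <- b$parent
      }
      branchesOut[[id]] <- NULL
      contracted <- TRUE
      break
    }
    if (!contracted) break
  }

  ## thinning retracts tips by roughly the tube radius; extend each leaf
  ## to the mask boundary along its end direction
  dmPx <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask)))
  parents2 <- vapply(branchesOut, function(b) b$parent, character(1))
  leaves <- setdiff(names(branchesOut), parents2)
  for (id in leaves) {
    path <- branchesOut[[id]]$path
    n <- nrow(path)
    if (n < 3L) next
    tip <- path[n, ]
    d <- unitVec(path[n, ] - path[max(1L, n - 4L), ])
    ## march along the end direction to the mask boundary
    ext <- 0
    for (step in seq(0.5, 8, by = 0.5)) {
      q <- tip + d * step
      i <- round(q[1]); j <- round(q[2])
      if (i < 1 || j < 1 || i > nrow(mask) || j > ncol(mask) ||
          !mask[i, j]) break
      ext <- step
    }
    ext <- ext - 0.5    # stay just inside the boundary pixel
    if (ext > 0.4)
      branchesOut[[id]]$path <- rbind(path, tip + d * ext)
  }
  polysUm <- lapply(branchesOut, function(b) .smoothPolyline(toUm(b$path)))
  ## snap each child's first vertex onto its (smoothed) parent polyline
  for (id in names(polysUm)) {
    par <- branchesOut[[id]]$parent
    if (is.na(par) || !(par %in% names(polysUm))) next
    polysUm[[id]][1, ] <- nearestPolylinePoint(polysUm[[id]][1, ],
                                               polysUm[[par]])
  }
  out <- lapply(names(branchesOut), function(id)
    .newBranch(id, branchesOut[[id]]$parent, polysUm[[id]]))
  rootStart <- if (length(out)) out[[1]]@polyline[1, ] else entry_hint
  new("ArborTree", entryPoint = rootStart, ganglionWidth = .FOV[1],
      branches = unname(out), genotype = "traced",
      cyclesBroken = bc$broke)
}

#' Detect varicosities along a traced arbor
#'
#' A point on a branch is a varicosity iff its local full width (twice the
#' medial-axis distance to the mask edge) exceeds
#' `varicosity_width_factor` times the median branch width AND its local
#' intensity exceeds `varicosity_intensity_factor` times the median on-axon
#' intensity; maxima closer than the separation floor are merged, and
#' detections within 2 um of a junction are discarded (junction geometry
#' mimics a swelling).
#'
#' @param projection intensity projection matrix.
#' @param tree the [ArborTree-class] extracted from this projection.
#' @param mask the axon mask used for extraction.
#' @param params from [traceParams()].
#' @param pixel_size micrometers per pixel.
#' @param origin (x, y) of pixel (1, 1), micrometers.
#' @return The tree with per-branch varicosities attached; skipped branches
#'   (shorter than 3 px) are listed in `attr(, "skipped")`.
#' @export
detectVaricosities <- function(projection, tree, mask,
                               params = traceParams(), pixel_size = 0.5,
                               origin = c(0, 0)) {
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask)))
  widthUm <- 2 * dm * pixel_size
  nx <- nrow(projection); ny <- ncol(projection)
  sampleAt <- function(poly) {
    q <- resamplePolyline(poly, pixel_size)
    i <- pmin(pmax(round((q[, 1] - origin[1]) / pixel_size) + 1L, 1L), nx)
    j <- pmin(pmax(round((q[, 2] - origin[2]) / pixel_size) + 1L, 1L), ny)
    arc <- c(0, cumsum(sqrt(rowSums(diff(q)^2))))
    list(w = widthUm[cbind(i, j)], I = projection[cbind(i, j)], arc = arc)
  }
  ids <- vapply(tree@branches, function(b) b@id, character(1))
  parents <- vapply(tree@branches, function(b) b@parentId, character(1))
  samples <- lapply(tree@branches, function(b) {
    if (b@length < 3 * pixel_size) return(NULL)
    sampleAt(b@polyline)
  })
  skipped <- ids[vapply(samples, is.null, logical(1))]
  allW <- unlist(lapply(samples, function(s) s$w))
  allI <- unlist(lapply(samples, function(s) s$I))
  medW <- stats::median(allW)
  medI <- stats::median(allI)
  exclude <- 1.2  # um around junctions

  br <- tree@branches
  for (bi in seq_along(br)) {
    s <- samples[[bi]]
    if (is.null(s)) next
    hot <- s$w > params$varicosity_width_factor * medW &
      s$I > params$varicosity_intensity_factor * medI
    ## exclusion zones: branch start (always a junction or the root) and the
    ## end when the branch has children
    hot[s$arc < exclude] <- FALSE
    if (ids[bi] %in% parents)
      hot[s$arc > max(s$arc) - exclude] <- FALSE
    if (!any(hot)) {
      br[[bi]]@varicosities <- data.frame(arc_position = numeric(0),
                                          diameter = numeric(0),
                                          intensity_gain = numeric(0))
      next
    }
    ## local intensity maxima inside hot stretches (a single run can carry
    ## several varicosities)
    half <- max(1L, ceiling(params$min_varicosity_separation_um / 2 /
                            pixel_size))
    n <- length(s$I)
    peaks <- NULL
    for (i in which(hot)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      if (s$I[i] >= max(s$I[lo:hi])) {
        peaks <- rbind(peaks, c(arc = s$arc[i], w = s$w[i], I = s$I[i]))
      }
    }
    if (is.null(peaks)) {
      br[[bi]]@varicosities <- data.frame(arc_position = numeric(0),
                                          diameter = numeric(0),
                                          intensity_gain = numeric(0))
      next
    }
    ## merge peaks closer than the separation floor (keep the brighter)
    if (nrow(peaks) > 1L) {
      peaks <- peaks[order(peaks[, "arc"]), , drop = FALSE]
      keep <- rep(TRUE, nrow(peaks))
      for (k in 2:nrow(peaks)) {
        prev <- max(which(keep[1:(k - 1)]))
        if (peaks[k, "arc"] - peaks[prev, "arc"] <
            params$min_varicosity_separation_um) {
          if (peaks[k, "I"] > peaks[prev, "I"]) keep[prev] <- FALSE
          else keep[k] <- FALSE
        }
      }
      peaks <- peaks[keep, , drop = FALSE]
    }
    br[[bi]]@varicosities <- data.frame(
      arc_position = pmin(peaks[, "arc"], br[[bi]]@length),
      diameter = peaks[, "w"],
      intensity_gain = peaks[, "I"] / medI)
  }
  out <- tree
  out@branches <- br
  attr(out, "skipped") <- skipped
  out
}

#' Trace a rendered stack end to end
#'
#' Convenience wrapper: [projectAndSegment()], [extractTree()],
#' [detectVaricosities()].
#'
#' @param stack a single-channel [ImageStack-class].
#' @param entry_hint (x, y) hint in arbor coordinates (defaults to the
#'   stack origin corner plus a nominal entry).
#' @param params from [traceParams()].
#' @return A traced [ArborTree-class] with varicosities.
#' @export
traceStack <- function(stack, entry_hint = NULL, params = traceParams()) {
  seg <- projectAndSegment(stack, params)
  if (is.null(entry_hint)) entry_hint <- stack@origin + c(25, 30)
  tr <- extractTree(seg$mask, seg$projection, entry_hint, params,
                    pixel_size = stack@pixelSize, origin = stack@origin)
  detectVaricosities(seg$projection, tr, seg$mask, params,
                     pixel_size = stack@pixelSize, origin = stack@origin)
}
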