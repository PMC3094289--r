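## Consensus-skeleton extraction, branch correspondence and classification.
##
## Branch correspondence is hierarchical: the observed root is matched to the
## template root, then at every matched pair the two sets of child branches
## ("broods") are put in optimal one-to-one correspondence by minimum-cost
## assignment under the descriptor distance, gated; the recursion descends
## only into matched pairs.  Descendants of an unmatched observed branch are
## variable; descendants of an unmatched template branch are missing.

#' Consensus / matching parameters
#'
#' @param freq_threshold presence frequency above which (strictly) a branch
#'   belongs to the consensus skeleton.
#' @param descriptor_weights nonnegative weights of the four descriptor
#'   terms: attach fraction, depth, direction, relative length.
#' @param gate_distance maximum assignable descriptor cost.
#' @param routing_angle direction deviation (radians) above which an assigned
#'   branch is flagged as a routing error.
#' @param dir_ref reference angle (radians) at which the direction term
#'   reaches 1.
#' @return Named list of parameters.
#' @export
consensusParams <- function(freq_threshold = 0.8,
                            descriptor_weights = c(attach = 1, depth = 1,
                                                   direction = 1, length = 0.5),
                            gate_distance = 1.0,
                            routing_angle = 45 * pi / 180,
                            dir_ref = 80 * pi / 180) {
  stopifnot(freq_threshold > 0, freq_threshold < 1,
            all(descriptor_weights >= 0), any(descriptor_weights > 0),
            gate_distance > 0)
  list(freq_threshold = freq_threshold,
       descriptor_weights = descriptor_weights,
       gate_distance = gate_distance,
       routing_angle = routing_angle,
       dir_ref = dir_ref)
}

## ---------------------------------------------------------------------------
## descriptors

## initial unit direction of a branch: first vertex toward the point ~10 um
## (or half the branch) along the arc
.branchDirection <- function(b) {
  at <- min(10, b@length / 2)
  unitVec(polylinePoint(b@polyline, at) - b@polyline[1, ])
}

#' Branch descriptors of a tree
#'
#' @param tree an [ArborTree-class].
#' @return data.frame with `id`, `parent_id`, `attach_fraction`, `depth`,
#'   `dir_x`, `dir_y`, `length` per branch.
#' @export
branchDescriptors <- function(tree) {
  br <- tree@branches
  idx <- .branchIndex(tree)
  out <- data.frame(
    id = vapply(br, function(b) b@id, character(1)),
    parent_id = vapply(br, function(b) b@parentId, character(1)),
    attach_fraction = NA_real_, depth = NA_integer_,
    dir_x = NA_real_, dir_y = NA_real_,
    length = vapply(br, function(b) b@length, numeric(1)),
    stringsAsFactors = FALSE)
  ## cumulative arcs per branch, for attachment-fraction lookups
  arcs <- lapply(br, function(b)
    c(0, cumsum(sqrt(rowSums(diff(b@polyline)^2)))))
  for (i in seq_along(br)) {
    b <- br[[i]]
    d <- .branchDirection(b)
    out$dir_x[i] <- d[1]; out$dir_y[i] <- d[2]
    if (is.na(b@parentId)) {
      out$attach_fraction[i] <- 0
      out$depth[i] <- 0L
    } else {
      j <- idx[[b@parentId]]
      pp <- br[[j]]@polyline
      ## arc position of the child's first vertex along the parent
      p0 <- b@polyline[1, ]
      dd <- (pp[, 1] - p0[1])^2 + (pp[, 2] - p0[2])^2
      vi <- which.min(dd)
      out$attach_fraction[i] <- min(1, arcs[[j]][vi] /
                                     max(br[[j]]@length, 1e-9))
      out$depth[i] <- out$depth[j] + 1L
    }
  }
  out
}

## descriptor cost between template branches (indices ti into the tplD
## vectors) and observed branches (indices oi into obsD); returns
## |ti| x |oi| cost matrix plus the direction angles
.descriptorCost <- function(tplD, ti, obsD, oi, scale, params) {
  w <- params$descriptor_weights
  costh <- pmin(pmax(outer(tplD$dx[ti], obsD$dx[oi]) +
                     outer(tplD$dy[ti], obsD$dy[oi]), -1), 1)
  ang <- acos(costh)
  lt <- scale * tplD$len[ti]
  lo <- obsD$len[oi]
  cost <- w[["attach"]] * abs(outer(tplD$attach[ti], obsD$attach[oi], "-")) +
    w[["depth"]] * abs(outer(tplD$depth[ti], obsD$depth[oi], "-")) +
    w[["direction"]] * (1 - costh) / (1 - cos(params$dir_ref)) +
    w[["length"]] * abs(outer(lt, lo, "-")) / outer(lt, lo, "+")
  list(cost = cost, angle = ang)
}

## one gated brood assignment; assign argument selects the solver
.broodAssign <- function(cost, gate, solver) {
  nt <- nrow(cost); no <- ncol(cost)
  n <- max(nt, no)
  if (n == 0L) return(list(pairs = cbind(integer(0), integer(0)), total = 0))
  padded <- matrix(gate, n, n)
  padded[seq_len(nt), seq_len(no)] <- pmin(cost, gate)
  a <- solver(padded)
  pairs <- NULL
  for (i in seq_len(nt)) {
    j <- a[i]
    if (j <= no && cost[i, j] <= gate - 1e-12)
      pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs)) pairs <- cbind(integer(0), integer(0))
  list(pairs = pairs, total = attr(a, "total"))
}

## ---------------------------------------------------------------------------

## template helpers: children lists and depth
.tplChildren <- function(tb) {
  lapply(tb$id, function(id) which(!is.na(tb$parent_id) & tb$parent_id == id))
}
.tplDepth <- function(tb) {
  idx <- stats::setNames(seq_len(nrow(tb)), tb$id)
  d <- integer(nrow(tb))
  for (i in seq_len(nrow(tb)))
    d[i] <- if (is.na(tb$parent_id[i])) 0L else d[idx[[tb$parent_id[i]]]] + 1L
  d
}

#' Match an arbor's branches to a skeleton template
#'
#' Hierarchical optimal correspondence (see module comments). Matching is run
#' twice: a first pass estimates the global length scale from the assigned
#' pairs, a second pass matches at that scale.
#'
#' @param tree a filtered, normalized [ArborTree-class].
#' @param template a [SkeletonTemplate-class].
#' @param params from [consensusParams()].
#' @param exhaustive use the brute-force assignment oracle instead of the
#'   Hungarian solver (tests; broods of at most 8).
#' @param descriptors optional precomputed [branchDescriptors()] table for
#'   `tree` (avoids recomputation in iterative callers).
#' @return List with `assignments` (named character vector, template id ->
#'   observed branch id or `NA`), `unmatched_observed` (character vector),
#'   `routing` (named logical vector over assigned template ids), `cost`
#'   (total assigned descriptor cost plus gate penalty per unmatched observed
#'   branch) and `scale` (estimated global length scale).
#' @export
matchToTemplate <- function(tree, template, params = consensusParams(),
                            exhaustive = FALSE, descriptors = NULL) {
  tb <- template@branches
  solver <- if (exhaustive) bruteAssignment else solveAssignment
  tdepth <- .tplDepth(tb)
  tkids <- .tplChildren(tb)
  troots <- which(is.na(tb$parent_id))
  obs <- if (!is.null(descriptors)) descriptors
         else if (length(tree@branches)) branchDescriptors(tree) else NULL

  emptyResult <- function() {
    list(assignments = stats::setNames(rep(NA_character_, nrow(tb)), tb$id),
         unmatched_observed = character(0),
         routing = stats::setNames(logical(0), character(0)),
         cost = 0, scale = 1)
  }
  if (is.null(obs)) return(emptyResult())

  okids <- lapply(obs$id, function(id) which(!is.na(obs$parent_id) &
                                             obs$parent_id == id))
  oroots <- which(is.na(obs$parent_id))

  tplD <- list(attach = tb$attach_fraction, depth = as.numeric(tdepth),
               dx = tb$dir_x, dy = tb$dir_y, len = tb$mean_length)
  obsD <- list(attach = obs$attach_fraction, depth = as.numeric(obs$depth),
               dx = obs$dir_x, dy = obs$dir_y, len = obs$length)

  runPass <- function(scale) {
    assignments <- stats::setNames(rep(NA_character_, nrow(tb)), tb$id)
    routing <- stats::setNames(rep(FALSE, nrow(tb)), tb$id)
    matchedObs <- character(0)
    total <- 0
    pairsLen <- NULL   # matched (template mean, observed length) for rescale
    recurse <- function(tis, ois) {
      if (!length(tis) && !length(ois)) return()
      if (length(tis) && length(ois)) {
        dc <- .descriptorCost(tplD, tis, obsD, ois, scale, params)
        ba <- .broodAssign(dc$cost, params$gate_distance, solver)
        for (k in seq_len(nrow(ba$pairs))) {
          ti <- tis[ba$pairs[k, 1]]
          oi <- ois[ba$pairs[k, 2]]
          assignments[[tb$id[ti]]] <<- obs$id[oi]
          routing[[tb$id[ti]]] <<- dc$angle[ba$pairs[k, 1], ba$pairs[k, 2]] >
            params$routing_angle
          total <<- total + dc$cost[ba$pairs[k, 1], ba$pairs[k, 2]]
          matchedObs <<- c(matchedObs, obs$id[oi])
          pairsLen <<- rbind(pairsLen, c(tb$mean_length[ti], obs$length[oi]))
          recurse(tkids[[ti]], okids[[oi]])
        }
      } else if (length(ois)) {
        ## no template counterpart: observed subtree is variable
        for (oi in ois) recurse(integer(0), okids[[oi]])
      }
      ## unmatched template children need no recursion (all missing)
    }
    recurse(troots, oroots)
    unmatched <- setdiff(obs$id, matchedObs)
    list(assignments = assignments, routing = routing,
         unmatched_observed = unmatched,
         cost = total + params$gate_distance * length(unmatched),
         pairsLen = pairsLen)
  }

  p1 <- runPass(1)
  scale <- if (!is.null(p1$pairsLen) && sum(p1$pairsLen[, 1]) > 0)
    sum(p1$pairsLen[, 2]) / sum(p1$pairsLen[, 1]) else 1
  p2 <- runPass(scale)
  list(assignments = p2$assignments,
       unmatched_observed = p2$unmatched_observed,
       routing = p2$routing[!is.na(p2$assignments)],
       cost = p2$cost, scale = scale)
}

#' Classify an arbor's branches against a template
#'
#' Writes `skeletal:<template id>` / `variable` labels and routing flags onto
#' the branches and reports the counts.
#'
#' @inheritParams matchToTemplate
#' @return List with `tree` (labeled [ArborTree-class]), `n_skeletal`,
#'   `n_variable`, `n_missing_skeletal`, `n_routing_errors` and `match` (the
#'   [matchToTemplate()] result).
#' @export
classifyBranches <- function(tree, template, params = consensusParams()) {
  m <- matchToTemplate(tree, template, params)
  byObs <- stats::setNames(names(m$assignments), m$assignments)
  br <- lapply(tree@branches, function(b) {
    if (b@id %in% m$assignments) {
      tid <- byObs[[b@id]]
      b@label <- paste0("skeletal:", tid)
      b@routingError <- isTRUE(m$routing[[tid]])
    } else {
      b@label <- "variable"
      b@routingError <- FALSE
    }
    b
  })
  out <- tree
  out@branches <- br
  list(tree = out,
       n_skeletal = sum(!is.na(m$assignments)),
       n_variable = length(m$unmatched_observed),
       n_missing_skeletal = sum(is.na(m$assignments)),
       n_routing_errors = sum(m$routing),
       match = m)
}

## ---------------------------------------------------------------------------
## consensus construction

## turn one arbor into an initial template (slot per branch)
.arborToTemplate <- function(tree) {
  d <- branchDescriptors(tree)
  data.frame(id = paste0("s", seq_len(nrow(d))),
             parent_id = ifelse(is.na(d$parent_id), NA_character_,
                                paste0("s", match(d$parent_id, d$id))),
             attach_fraction = ifelse(is.na(d$parent_id), 0, d$attach_fraction),
             dir_x = d$dir_x, dir_y = d$dir_y,
             mean_length = d$length, sd_length = 0.2 * d$length,
             presence_prob = 1, stringsAsFactors = FALSE)
}

#' Build a consensus skeleton from a cohort
#'
#' Iterative template construction: initialize from a deterministically
#' chosen seed arbor (most branches, ties by total length), then alternate
#' matching all arbors against the current template with re-estimating
#' per-slot descriptor means and presence frequencies (new slots are opened
#' for unmatched observed branches) until the assignments stabilize (at most
#' `max_rounds`). Returns the slots whose presence frequency strictly exceeds
#' the threshold, with statistics re-estimated in a final clean pass against
#' the converged skeleton.
#'
#' @param cohort nonempty list of filtered, normalized [ArborTree-class]
#'   objects.
#' @param params from [consensusParams()].
#' @param max_rounds maximum alternation rounds.
#' @param exhaustive use the brute-force assignment oracle (tests).
#' @return A [SkeletonTemplate-class]; `@converged` is `FALSE` when the
#'   assignments did not stabilize.
#' @export
buildConsensus <- function(cohort, params = consensusParams(),
                           max_rounds = 10L, exhaustive = FALSE) {
  stopifnot(length(cohort) >= 1)
  n <- length(cohort)
  nb <- vapply(cohort, nBranches, integer(1))
  tl <- vapply(cohort, function(t)
    sum(vapply(t@branches, function(b) b@length, numeric(1))), numeric(1))
  seedIdx <- order(-nb, -tl)[1]
  tb <- .arborToTemplate(cohort[[seedIdx]])
  tpl <- new("SkeletonTemplate", name = "consensus", branches = tb,
             freqThreshold = params$freq_threshold)

  descs <- lapply(cohort, function(t)
    if (nBranches(t)) branchDescriptors(t) else NULL)
  prevKey <- ""
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    acc <- .accumulateRound(cohort, tpl, params, exhaustive,
                            openSlots = TRUE, descs = descs)
    tpl <- acc$template
    if (identical(acc$key, prevKey)) { converged <- TRUE; break }
    prevKey <- acc$key
  }
  ## keep core slots only (frequency strictly above threshold); children of a
  ## dropped slot cannot stay (their frequency is never higher than the
  ## parent's, so this prunes consistently)
  tb <- tpl@branches
  keep <- tb$presence_prob > params$freq_threshold + 1e-12
  repeat {
    orphan <- keep & !is.na(tb$parent_id) & !(tb$parent_id %in% tb$id[keep])
    if (!any(orphan)) break
    keep[orphan] <- FALSE
  }
  tpl@branches <- tb[keep, , drop = FALSE]
  rownames(tpl@branches) <- NULL
  ## final clean re-estimation pass against the converged core (restores
  ## order invariance of the reported statistics)
  if (nrow(tpl@branches)) {
    acc <- .accumulateRound(cohort, tpl, params, exhaustive,
                            openSlots = FALSE, descs = descs)
    tpl <- acc$template
    tb <- tpl@branches
    ord <- order(.tplDepth(tb), -tb$presence_prob, tb$mean_length)
    tb <- tb[ord, , drop = FALSE]
    old2new <- stats::setNames(sprintf("c%02d", seq_len(nrow(tb))), tb$id)
    tb$id <- unname(old2new[tb$id])
    tb$parent_id <- ifelse(is.na(tb$parent_id), NA_character_,
                           unname(old2new[tb$parent_id]))
    ## reorder parents before children
    tpl <- makeTemplate(tb, name = "consensus",
                        freq_threshold = params$freq_threshold)
  }
  tpl@converged <- converged
  tpl
}

## one accumulation round: match every arbor, optionally opening new slots
## for unmatched observed branches, then re-estimate slot statistics
.accumulateRound <- function(cohort, tpl, params, exhaustive, openSlots,
                             descs = NULL) {
  tb <- tpl@branches
  stats <- list()   # slot id -> list(dirs, lens, attach, count)
  for (id in tb$id)
    stats[[id]] <- list(dir = NULL, len = NULL, attach = NULL, count = 0L)
  keyParts <- character(0)
  nextSlot <- nrow(tb)
  for (ai in seq_along(cohort)) {
    tree <- cohort[[ai]]
    tpl@branches <- tb
    obs <- if (!is.null(descs)) descs[[ai]]
           else if (nBranches(tree)) branchDescriptors(tree) else NULL
    m <- matchToTemplate(tree, tpl, params, exhaustive = exhaustive,
                         descriptors = obs)
    ## during iteration, lengths are de-scaled per arbor to align animals;
    ## the final (closed-slot) pass records raw lengths, which fixes the
    ## template's overall scale to data units independently of the
    ## iteration history
    sc <- if (openSlots) m$scale else 1
    for (tid in names(m$assignments)) {
      oid <- m$assignments[[tid]]
      if (is.na(oid)) next
      o <- obs[obs$id == oid, ]
      st <- stats[[tid]]
      st$dir <- rbind(st$dir, c(o$dir_x, o$dir_y))
      st$len <- c(st$len, o$length / sc)
      st$attach <- c(st$attach, o$attach_fraction)
      st$count <- st$count + 1L
      stats[[tid]] <- st
    }
    keyParts <- c(keyParts, paste(m$assignments, collapse = ","))
    if (openSlots && length(m$unmatched_observed)) {
      byObs <- stats::setNames(names(m$assignments), m$assignments)
      for (oid in m$unmatched_observed) {
        o <- obs[obs$id == oid, ]
        parentSlot <- NA_character_
        if (!is.na(o$parent_id) && o$parent_id %in% names(byObs))
          parentSlot <- byObs[[o$parent_id]]
        else if (!is.na(o$parent_id)) next  # parent itself unmatched: skip
        nextSlot <- nextSlot + 1L
        nid <- paste0("s", nextSlot)
        tb <- rbind(tb, data.frame(
          id = nid, parent_id = parentSlot,
          attach_fraction = ifelse(is.na(o$parent_id), 0, o$attach_fraction),
          dir_x = o$dir_x, dir_y = o$dir_y,
          mean_length = o$length / sc, sd_length = 0.2 * o$length / sc,
          presence_prob = 0, stringsAsFactors = FALSE))
        stats[[nid]] <- list(dir = matrix(c(o$dir_x, o$dir_y), 1),
                             len = o$length / sc, attach = o$attach_fraction,
                             count = 1L)
      }
    }
  }
  ## re-estimate slot statistics
  n <- length(cohort)
  for (i in seq_len(nrow(tb))) {
    st <- stats[[tb$id[i]]]
    if (st$count > 0L) {
      d <- unitVec(colMeans(st$dir))
      tb$dir_x[i] <- d[1]; tb$dir_y[i] <- d[2]
      tb$mean_length[i] <- mean(st$len)
      tb$sd_length[i] <- if (st$count > 1L) stats::sd(st$len)
                         else 0.2 * mean(st$len)
      tb$attach_fraction[i] <- ifelse(is.na(tb$parent_id[i]), 0,
                                      min(1, max(0, mean(st$attach))))
    }
    tb$presence_prob[i] <- stats[[tb$id[i]]]$count / n
  }
  tpl@branches <- tb
  list(template = tpl, key = paste(keyParts, collapse = ";"))
}

#' Default entry-region map
#'
#' Anterior-posterior bands of the thoracic ganglion in micrometers; a
#' correct entry lies in the mesothoracic band.
#'
#' @return data.frame with `region`, `ymin`, `ymax`.
#' @export
regionMap <- function() {
  data.frame(region = c("mesothoracic", "metathoracic"),
             ymin = c(0, 120), ymax = c(120, 260),
             stringsAsFactors = FALSE)
}

#' Score an arbor's CNS entry as a guidance error
#'
#' @param tree an [ArborTree-class].
#' @param region_map data.frame as from [regionMap()].
#' @return `TRUE` iff the entry point falls outside the mesothoracic band.
#' @export
classifyEntry <- function(tree, region_map = regionMap()) {
  y <- tree@entryPoint[2]
  hit <- which(y >= region_map$ymin & y < region_map$ymax)
  if (!length(hit))
    stop(sprintf("entry point y = %.1f um outside all mapped bands", y))
  region_map$region[hit[1]] != "mesothoracic"
}
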