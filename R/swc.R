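## SWC serialization of ArborTree objects.
##
## Standard single-neuron SWC (id type x y z radius parent), one sample per
## polyline vertex, type 2 (axon).  Branch structure, labels, routing flags
## and tree-level metadata ride in `#` header comments so a written tree
## round-trips exactly; varicosities go to a sidecar CSV (SWC has no bouton
## field).

#' Write an arbor to SWC (+ varicosity sidecar CSV)
#'
#' @param tree an [ArborTree-class].
#' @param path output `.swc` path.
#' @param varicosity_path sidecar CSV path; default replaces the extension
#'   with `_varicosities.csv`. Columns: `branch_id`, `arc_position_um`,
#'   `diameter_um`, `intensity_gain`.
#' @return Invisibly, `path`.
#' @export
writeSWC <- function(tree, path,
                     varicosity_path = sub("\\.swc$", "_varicosities.csv",
                                           path)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# genotype: %s", tree@genotype),
    sprintf("# entry_point: %.6f %.6f", tree@entryPoint[1], tree@entryPoint[2]),
    sprintf("# entry_region: %s", tree@entryRegion),
    sprintf("# ganglion_width: %.6f", tree@ganglionWidth),
    sprintf("# guidance_error: %s", tree@guidanceError),
    sprintf("# cycles_broken: %s", tree@cyclesBroken)), con)
  rows <- character(0)
  nid <- 0L
  vertexNodes <- list()  # branch id -> SWC ids of its polyline vertices
  polys <- stats::setNames(lapply(tree@branches, function(b) b@polyline),
                           vapply(tree@branches, function(b) b@id,
                                  character(1)))
  for (b in tree@branches) {
    p <- b@polyline
    if (is.na(b@parentId)) {
      attach <- "root"
      parentNode <- -1L
      start <- 1L
    } else {
      pp <- polys[[b@parentId]]
      atEnd <- sqrt(sum((p[1, ] - pp[nrow(pp), ])^2)) < 1e-6
      ## nearest parent vertex carries the SWC parent link
      j <- which.min(rowSums(sweep(pp, 2, p[1, ])^2))
      parentNode <- vertexNodes[[b@parentId]][j]
      if (atEnd) { attach <- "end"; start <- 2L }
      else { attach <- "mid"; start <- 1L }
    }
    writeLines(sprintf("# branch: %s parent=%s label=%s routing=%s n=%d attach=%s",
                       b@id, ifelse(is.na(b@parentId), "NA", b@parentId),
                       b@label, b@routingError, nrow(p) - start + 1L, attach),
               con)
    vn <- integer(0)
    if (start == 2L) vn <- parentNode
    for (v in seq(start, nrow(p))) {
      nid <- nid + 1L
      rows <- c(rows, sprintf("%d 2 %.6f %.6f 0.000000 0.750000 %d",
                              nid, p[v, 1], p[v, 2], parentNode))
      parentNode <- nid
      vn <- c(vn, nid)
    }
    vertexNodes[[b@id]] <- vn
  }
  writeLines(rows, con)
  vv <- do.call(rbind, lapply(tree@branches, function(b) {
    if (!nrow(b@varicosities)) return(NULL)
    data.frame(branch_id = b@id,
               arc_position_um = b@varicosities$arc_position,
               diameter_um = b@varicosities$diameter,
               intensity_gain = b@varicosities$intensity_gain)
  }))
  if (is.null(vv))
    vv <- data.frame(branch_id = character(0), arc_position_um = numeric(0),
                     diameter_um = numeric(0), intensity_gain = numeric(0))
  utils::write.csv(vv, varicosity_path, row.names = FALSE)
  invisible(path)
}

#' Read an arbor written by [writeSWC()]
#'
#' @param path `.swc` path.
#' @param varicosity_path sidecar CSV (optional; missing file means no
#'   varicosities).
#' @return The reconstructed [ArborTree-class].
#' @export
readSWC <- function(path,
                    varicosity_path = sub("\\.swc$", "_varicosities.csv",
                                          path)) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key, default = NA_character_) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  samples <- utils::read.table(text = lines[!grepl("^#", lines)],
                               col.names = c("id", "type", "x", "y", "z",
                                             "radius", "parent"))
  binfo <- grep("^# branch:", hdr, value = TRUE)
  bmeta <- do.call(rbind, lapply(binfo, function(l) {
    f <- strsplit(trimws(sub("^# branch:", "", l)), " ")[[1]]
    data.frame(id = f[1],
               parent = sub("^parent=", "", f[2]),
               label = sub("^label=", "", f[3]),
               routing = sub("^routing=", "", f[4]),
               n = as.integer(sub("^n=", "", f[5])),
               attach = sub("^attach=", "", f[6]),
               stringsAsFactors = FALSE)
  }))
  vv <- if (file.exists(varicosity_path))
    utils::read.csv(varicosity_path, stringsAsFactors = FALSE)
  else data.frame(branch_id = character(0), arc_position_um = numeric(0),
                  diameter_um = numeric(0), intensity_gain = numeric(0))

  ## split the sample chain back into branches: a new branch starts where the
  ## parent sample is the recorded end of another branch or -1
  xy <- as.matrix(samples[, c("x", "y")])
  branchesOut <- list()
  ends <- list()
  if (nrow(samples) && !is.null(bmeta)) {
    ## split the sample rows by the per-branch vertex counts in the header
    ends_at <- cumsum(bmeta$n)
    starts_at <- c(1L, utils::head(ends_at, -1L) + 1L)
    for (k in seq_len(nrow(bmeta))) {
      rows <- seq(starts_at[k], ends_at[k])
      meta <- bmeta[k, ]
      par <- meta$parent
      poly <- xy[rows, , drop = FALSE]
      if (identical(meta$attach, "end")) {
        ## prepend the shared vertex (parent branch end)
        poly <- rbind(ends[[par]], poly)
      }
      vb <- vv[vv$branch_id == meta$id, , drop = FALSE]
      branchesOut[[meta$id]] <-
        .newBranch(meta$id, if (par == "NA") NA_character_ else par, poly,
                   varicosities = data.frame(
                     arc_position = vb$arc_position_um,
                     diameter = vb$diameter_um,
                     intensity_gain = vb$intensity_gain),
                   label = meta$label,
                   routingError = identical(meta$routing, "TRUE"))
      ends[[meta$id]] <- poly[nrow(poly), ]
    }
  }
  ep <- as.numeric(strsplit(getv("entry_point", "0 0"), " +")[[1]])
  new("ArborTree",
      entryPoint = ep,
      entryRegion = getv("entry_region", "mesothoracic"),
      ganglionWidth = as.numeric(getv("ganglion_width", "135")),
      branches = unname(branchesOut),
      genotype = getv("genotype", "unknown"),
      guidanceError = identical(getv("guidance_error", "FALSE"), "TRUE"),
      cyclesBroken = identical(getv("cycles_broken", "FALSE"), "TRUE"))
}
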