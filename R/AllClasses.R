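#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core S4 containers.  A Branch is one countable axonal segment (a maximal
## path between branch points, or from a branch point to a tip); an ArborTree
## is the rooted collection of branches of one neuron; a SkeletonTemplate is
## the prototypical branch set with per-branch geometry statistics and
## presence frequencies; a GenotypeConfig holds the generative parameters of
## one cohort; an ImageStack is a calibrated voxel grid.
## ---------------------------------------------------------------------------

#' Branch: one axonal segment
#'
#' A branch is a maximal centerline path between topological branch points (or
#' from a branch point to a tip); the root trunk counts as a branch. Children
#' attach at the final vertex of their parent's polyline.
#'
#' @slot id character branch identifier, unique within a tree.
#' @slot parentId character id of the parent branch, or `NA` for the root.
#' @slot polyline two-column numeric matrix of (x, y) vertices in micrometers.
#' @slot length numeric arc length of the polyline in micrometers.
#' @slot varicosities data.frame with columns `arc_position` (um along the
#'   branch), `diameter` (um) and `intensity_gain` (multiplier over the axon
#'   shaft intensity).
#' @slot label character; one of `"skeletal:<template id>"`, `"variable"`, or
#'   `"unassigned"`.
#' @slot routingError logical; `TRUE` when the branch follows an abnormal
#'   trajectory (direction deviating more than 45 degrees from the
#'   stereotyped one).
#' @export
setClass("Branch", representation(
  id = "character", parentId = "character", polyline = "matrix",
  length = "numeric", varicosities = "data.frame", label = "character",
  routingError = "logical"
), prototype(
  id = "b", parentId = NA_character_,
  polyline = cbind(c(0, 1), c(0, 0)), length = 1,
  varicosities = data.frame(arc_position = numeric(0), diameter = numeric(0),
                            intensity_gain = numeric(0)),
  label = "unassigned", routingError = FALSE
))

setValidity("Branch", function(object) {
  msg <- character(0)
  if (ncol(object@polyline) != 2L) msg <- c(msg, "polyline must have 2 columns")
  arc <- polylineLength(object@polyline)
  if (arc <= 0) msg <- c(msg, "branch length must be positive")
  if (abs(object@length - arc) > 1e-6 * max(arc, 1))
    msg <- c(msg, "length does not equal polyline arc length")
  v <- object@varicosities
  if (nrow(v) && (any(v$arc_position < -1e-9) ||
                  any(v$arc_position > object@length + 1e-9)))
    msg <- c(msg, "varicosity arc_position outside [0, length]")
  if (length(msg)) msg else TRUE
})

#' ArborTree: the branched arbor of one neuron
#'
#' @slot entryPoint numeric (x, y) position, in micrometers, where the axon
#'   enters the thoracic ganglion; used for guidance-error scoring.
#' @slot entryRegion character; `"mesothoracic"` (correct) or
#'   `"metathoracic"` (guidance error).
#' @slot ganglionWidth numeric ganglion width in micrometers; the
#'   size-normalization reference for this animal.
#' @slot branches list of [Branch-class] objects, parents before children.
#' @slot genotype character cohort label.
#' @slot guidanceError logical; axon entered through the wrong nerve pathway.
#' @slot cyclesBroken logical; set by the tracer when centerline cycles had to
#'   be broken.
#' @export
setClass("ArborTree", representation(
  entryPoint = "numeric", entryRegion = "character", ganglionWidth = "numeric",
  branches = "list", genotype = "character", guidanceError = "logical",
  cyclesBroken = "logical"
), prototype(
  entryPoint = c(0, 0), entryRegion = "mesothoracic", ganglionWidth = 135,
  branches = list(), genotype = "unknown", guidanceError = FALSE,
  cyclesBroken = FALSE
))

setValidity("ArborTree", function(object) {
  msg <- character(0)
  if (length(object@entryPoint) != 2L) msg <- c(msg, "entryPoint must be (x, y)")
  if (object@ganglionWidth <= 0) msg <- c(msg, "ganglionWidth must be positive")
  br <- object@branches
  if (length(br)) {
    ids <- vapply(br, function(b) b@id, character(1))
    if (anyDuplicated(ids)) msg <- c(msg, "duplicate branch ids")
    pid <- vapply(br, function(b) b@parentId, character(1))
    nroot <- sum(is.na(pid))
    if (nroot != 1L) msg <- c(msg, "tree must have exactly one root branch")
    known <- pid[!is.na(pid)]
    if (!all(known %in% ids)) msg <- c(msg, "parentId refers to unknown branch")
    ## connectivity: child's first vertex lies on the parent's polyline
    ## (endpoint for stereotyped daughters, interior for interstitial
    ## branches); 1 um tolerance absorbs centerline smoothing in traced trees
    idx <- stats::setNames(seq_along(br), ids)
    for (b in br) {
      if (is.na(b@parentId)) next
      pp <- br[[idx[[b@parentId]]]]@polyline
      if (pointPolylineDistance(b@polyline[1, ], pp) > 1)
        msg <- c(msg, sprintf("branch %s detached from parent", b@id))
    }
  }
  if (length(msg)) msg else TRUE
})

#' SkeletonTemplate: prototypical branch set of a genotype
#'
#' Branch rows are ordered parents-before-children. `presence_prob` values are
#' marginal presence frequencies; `attach_fraction` is the fraction of the
#' parent's arc length at which the branch attaches (1 = parent endpoint).
#'
#' @slot name character template name.
#' @slot branches data.frame with columns `id`, `parent_id`, `attach_fraction`,
#'   `dir_x`, `dir_y` (unit direction at origin), `mean_length`, `sd_length`
#'   (um) and `presence_prob`.
#' @slot freqThreshold numeric; branches above this presence frequency
#'   (strictly greater) are "core"/skeletal.
#' @slot converged logical; `FALSE` when an iteratively built consensus did
#'   not stabilize.
#' @export
setClass("SkeletonTemplate", representation(
  name = "character", branches = "data.frame", freqThreshold = "numeric",
  converged = "logical"
), prototype(name = "template", freqThreshold = 0.8, converged = TRUE))

setValidity("SkeletonTemplate", function(object) {
  b <- object@branches
  need <- c("id", "parent_id", "attach_fraction", "dir_x", "dir_y",
            "mean_length", "sd_length", "presence_prob")
  if (!all(need %in% names(b))) return("missing template branch columns")
  msg <- character(0)
  if (anyDuplicated(b$id)) msg <- c(msg, "branch ids must be unique")
  if (any(b$mean_length <= 0)) msg <- c(msg, "mean_length must be positive")
  if (any(b$attach_fraction < 0 | b$attach_fraction > 1))
    msg <- c(msg, "attach_fraction must be in [0, 1]")
  if (any(b$presence_prob < 0 | b$presence_prob > 1))
    msg <- c(msg, "presence_prob must be in [0, 1]")
  if (object@freqThreshold <= 0 || object@freqThreshold >= 1)
    msg <- c(msg, "freqThreshold must be in (0, 1)")
  known <- b$parent_id[!is.na(b$parent_id)]
  if (!all(known %in% b$id)) msg <- c(msg, "parent_id refers to unknown branch")
  ## parents must precede children (also rules out cycles)
  pos <- stats::setNames(seq_len(nrow(b)), b$id)
  par <- b$parent_id
  if (any(!is.na(par) & pos[par] >= seq_len(nrow(b))))
    msg <- c(msg, "branches must be ordered parents before children")
  if (length(msg)) msg else TRUE
})

#' GenotypeConfig: generative parameters of one cohort
#'
#' Target fields are transcribed per-genotype summary statistics (mean and
#' SEM of branch count, total arbor size and varicosity count, guidance-error
#' frequency, cohort size). Free generator parameters (`variableBranchRate`,
#' `lengthScale`, `varicosityDensity`, `skeletonPresenceScale` and the
#' dispersion knobs) are filled in by [calibrateConfig()].
#'
#' @slot name character genotype label.
#' @slot nAnimals integer cohort size.
#' @slot targets named numeric: `branch_mean`, `branch_sem`, `total_len_mean`,
#'   `total_len_sem`, `varicosity_mean`, `varicosity_sem`, `skeletal_mean`.
#' @slot guidanceErrorRate numeric in `[0, 1]`.
#' @slot routingErrorRate numeric in `[0, 1]`.
#' @slot variableBranchRate numeric; expected number of variable branches
#'   drawn (pre 4-um filter).
#' @slot variableBranchSD numeric dispersion of the variable-branch count.
#' @slot lengthScale numeric global multiplier on template branch lengths.
#' @slot varicosityDensity numeric varicosities per micrometer of kept arbor.
#' @slot skeletonPresenceScale numeric multiplier on non-obligate skeletal
#'   presence marginals.
#' @slot lengthDispCV numeric CV of the per-animal arbor-size factor.
#' @slot varicosityDispCV numeric CV of the per-animal varicosity-density
#'   factor.
#' @slot calibrated logical; set by [calibrateConfig()].
#' @slot seed integer default seed for cohort generation.
#' @export
setClass("GenotypeConfig", representation(
  name = "character", nAnimals = "integer", targets = "numeric",
  guidanceErrorRate = "numeric", routingErrorRate = "numeric",
  variableBranchRate = "numeric", variableBranchSD = "numeric",
  lengthScale = "numeric", varicosityDensity = "numeric",
  skeletonPresenceScale = "numeric", lengthDispCV = "numeric",
  varicosityDispCV = "numeric", calibrated = "logical", seed = "integer"
), prototype(
  guidanceErrorRate = 0, routingErrorRate = 0, variableBranchRate = 0,
  variableBranchSD = 0, lengthScale = 1, varicosityDensity = 0,
  skeletonPresenceScale = 1, lengthDispCV = 0, varicosityDispCV = 0,
  calibrated = FALSE, seed = 1L
))

setValidity("GenotypeConfig", function(object) {
  msg <- character(0)
  need <- c("branch_mean", "branch_sem", "total_len_mean", "total_len_sem",
            "varicosity_mean", "varicosity_sem", "skeletal_mean")
  if (!all(need %in% names(object@targets)))
    msg <- c(msg, paste("targets must contain", paste(need, collapse = ", ")))
  else {
    t <- object@targets
    if (t[["branch_mean"]] <= 0 || t[["total_len_mean"]] <= 0 ||
        t[["varicosity_mean"]] < 0)
      msg <- c(msg, "target means must be positive")
  }
  if (object@nAnimals < 1L) msg <- c(msg, "n_animals must be >= 1")
  for (f in c("guidanceErrorRate", "routingErrorRate")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, paste(f, "must be in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' ImageStack: calibrated fluorescence voxel grid
#'
#' @slot voxels 4-D numeric array `[x, y, z, channel]` of nonnegative
#'   intensities in `[0, 1]`.
#' @slot pixelSize numeric micrometers per pixel (x and y).
#' @slot zStep numeric micrometers between focal planes.
#' @slot origin numeric (x, y); position, in the coordinate frame of the
#'   rendered arbor, of the center of pixel (1, 1).
#' @slot degraded logical; `TRUE` when the renderer flagged that the pixel
#'   size undersamples the axon width.
#' @export
setClass("ImageStack", representation(
  voxels = "array", pixelSize = "numeric", zStep = "numeric",
  origin = "numeric", degraded = "logical"
), prototype(voxels = array(0, c(1, 1, 1, 1)), pixelSize = 0.5, zStep = 1,
             origin = c(0, 0), degraded = FALSE))

setValidity("ImageStack", function(object) {
  msg <- character(0)
  if (length(dim(object@voxels)) != 4L)
    msg <- c(msg, "voxels must be a 4-D array [x, y, z, channel]")
  if (any(object@voxels < 0)) msg <- c(msg, "intensities must be nonnegative")
  if (object@pixelSize <= 0 || object@zStep <= 0)
    msg <- c(msg, "calibration must be positive")
  if (length(msg)) msg else TRUE
})

## ------------------------------- show methods ------------------------------

setMethod("show", "ArborTree", function(object) {
  cat(sprintf("ArborTree (%s): %d branches, %.1f um total, %d varicosities\n",
              object@genotype, length(object@branches),
              sum(vapply(object@branches, function(b) b@length, numeric(1))),
              sum(vapply(object@branches, function(b) nrow(b@varicosities),
                         integer(1)))))
  cat(sprintf("  entry: (%.1f, %.1f) [%s]%s; ganglion width %.1f um\n",
              object@entryPoint[1], object@entryPoint[2], object@entryRegion,
              if (object@guidanceError) " GUIDANCE ERROR" else "",
              object@ganglionWidth))
})

setMethod("show", "SkeletonTemplate", function(object) {
  b <- object@branches
  cat(sprintf("SkeletonTemplate '%s': %d branches (mean lengths %.0f-%.0f um), freq threshold > %.0f%%\n",
              object@name, nrow(b),
              if (nrow(b)) min(b$mean_length) else NA,
              if (nrow(b)) max(b$mean_length) else NA,
              100 * object@freqThreshold))
})

setMethod("show", "GenotypeConfig", function(object) {
  t <- object@targets
  cat(sprintf("GenotypeConfig '%s' (n=%d)%s\n", object@name, object@nAnimals,
              if (object@calibrated) " [calibrated]" else " [uncalibrated]"))
  cat(sprintf("  targets: %.1f branches, %.0f um, %.1f varicosities; guidance %.0f%%\n",
              t[["branch_mean"]], t[["total_len_mean"]], t[["varicosity_mean"]],
              100 * object@guidanceErrorRate))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d x %d px, %d slices, %d channel(s), %.2f um/px\n",
              d[1], d[2], d[3], d[4], object@pixelSize))
})

## ------------------------------ accessors ----------------------------------

#' @rdname ArborTree-class
#' @param tree an [ArborTree-class].
#' @return `branches()` returns the list of [Branch-class] objects.
#' @export
branches <- function(tree) tree@branches

#' Number of branches in a tree
#' @param tree an [ArborTree-class].
#' @export
nBranches <- function(tree) length(tree@branches)

#' Branch lengths of a tree
#' @param tree an [ArborTree-class].
#' @return Named numeric vector of branch arc lengths (um).
#' @export
branchLengths <- function(tree) {
  vapply(tree@branches, function(b) b@length, numeric(1),
         USE.NAMES = FALSE) |>
    stats::setNames(vapply(tree@branches, function(b) b@id, character(1)))
}

#' Total varicosity count of a tree
#' @param tree an [ArborTree-class].
#' @export
nVaricosities <- function(tree) {
  sum(vapply(tree@branches, function(b) nrow(b@varicosities), integer(1)))
}

#' Branch labels of a tree
#' @param tree an [ArborTree-class].
#' @export
branchLabels <- function(tree) {
  vapply(tree@branches, function(b) b@label, character(1))
}

#' Template branch table
#' @param template a [SkeletonTemplate-class].
#' @export
templateBranches <- function(template) template@branches

## internal: quick id -> index map
.branchIndex <- function(tree) {
  stats::setNames(seq_along(tree@branches),
                  vapply(tree@branches, function(b) b@id, character(1)))
}

## internal constructors used in hot paths (validity holds by construction;
## tests validate explicitly with validObject)
.newArborTree <- function(entryPoint, entryRegion, ganglionWidth, branches,
                          genotype, guidanceError) {
  t <- new("ArborTree")
  t@entryPoint <- entryPoint; t@entryRegion <- entryRegion
  t@ganglionWidth <- ganglionWidth; t@branches <- branches
  t@genotype <- genotype; t@guidanceError <- guidanceError
  t
}

.newBranch <- function(id, parentId, polyline, varicosities = NULL,
                       label = "unassigned", routingError = FALSE) {
  b <- new("Branch")
  b@id <- id; b@parentId <- parentId
  b@polyline <- polyline
  b@length <- polylineLength(polyline)
  if (!is.null(varicosities)) b@varicosities <- varicosities
  b@label <- label; b@routingError <- routingError
  b
}
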