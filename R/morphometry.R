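## Filtering, size normalization and per-arbor metrics.

#' Morphometry parameters
#'
#' @param min_branch_len countable-branch threshold in micrometers; branches
#'   are retained only when strictly longer than this after normalization.
#' @param reference_ganglion_width reference width (um) to which arbors are
#'   rescaled; `NA` means "use each tree's own width" (i.e. no rescaling) for
#'   single trees, or the cohort mean width in [filterCohort()].
#' @return Named list of parameters.
#' @export
morphometryParams <- function(min_branch_len = 4,
                              reference_ganglion_width = NA_real_) {
  stopifnot(min_branch_len > 0)
  list(min_branch_len = min_branch_len,
       reference_ganglion_width = reference_ganglion_width)
}

#' Normalize an arbor to the reference ganglion width and filter short branches
#'
#' All branch polylines (and the entry point) are scaled multiplicatively by
#' `reference / ganglionWidth`; branches whose scaled length is less than or
#' equal to `min_branch_len` are removed (strictly-greater retention), along
#' with their varicosities and any descendant branches. The tree's recorded
#' width becomes the reference, so the operation is idempotent.
#'
#' @param tree an [ArborTree-class].
#' @param params from [morphometryParams()].
#' @return The filtered, normalized [ArborTree-class].
#' @export
filterAndNormalize <- function(tree, params = morphometryParams()) {
  w <- tree@ganglionWidth
  if (!is.finite(w) || w <= 0) stop("ganglion width must be positive")
  ref <- params$reference_ganglion_width
  if (is.na(ref)) ref <- w
  sc <- ref / w
  br <- lapply(tree@branches, function(b) {
    b@polyline <- b@polyline * sc
    b@length <- b@length * sc
    b@varicosities$arc_position <- b@varicosities$arc_position * sc
    b
  })
  ## drop short branches together with their subtrees (a child cannot stay
  ## attached to a removed parent)
  keep <- vapply(br, function(b) b@length > params$min_branch_len, logical(1))
  ids <- vapply(br, function(b) b@id, character(1))
  pid <- vapply(br, function(b) b@parentId, character(1))
  repeat {
    orphan <- !is.na(pid) & !(pid %in% ids[keep]) & keep
    if (!any(orphan)) break
    keep[orphan] <- FALSE
  }
  out <- tree
  out@branches <- br[keep]
  out@ganglionWidth <- ref
  out@entryPoint <- tree@entryPoint * sc
  out
}

#' Filter and normalize a whole cohort
#'
#' The reference width defaults to the cohort mean ganglion width.
#'
#' @param cohort list of [ArborTree-class] objects.
#' @param params from [morphometryParams()]; an `NA` reference is replaced by
#'   the cohort mean width.
#' @return List of filtered, normalized trees.
#' @export
filterCohort <- function(cohort, params = morphometryParams()) {
  if (is.na(params$reference_ganglion_width))
    params$reference_ganglion_width <-
      mean(vapply(cohort, function(t) t@ganglionWidth, numeric(1)))
  lapply(cohort, filterAndNormalize, params = params)
}

#' Per-arbor morphometric summary
#'
#' @param tree a filtered, normalized [ArborTree-class].
#' @return One-row data.frame with `branch_count`, `total_length` (um),
#'   `varicosity_count`, `varicosities_per_branch`, `n_skeletal`,
#'   `n_variable`, `guidance_error`.
#' @examples
#' # a two-branch arbor with 10 + 20 um and 1 + 3 varicosities summarizes to
#' # (2, 30, 4, 2.0)
#' @export
summarizeArbor <- function(tree) {
  n <- length(tree@branches)
  tl <- sum(vapply(tree@branches, function(b) b@length, numeric(1)))
  nv <- sum(vapply(tree@branches, function(b) nrow(b@varicosities),
                   integer(1)))
  lab <- branchLabels(tree)
  data.frame(
    branch_count = n,
    total_length = tl,
    varicosity_count = nv,
    varicosities_per_branch = if (n > 0) nv / n else 0,
    n_skeletal = sum(startsWith(lab, "skeletal:")),
    n_variable = sum(lab == "variable"),
    guidance_error = tree@guidanceError)
}

#' Summarize a cohort into per-arbor metric rows
#'
#' @param cohort list of filtered [ArborTree-class] objects.
#' @param genotype optional genotype label override.
#' @return data.frame with one row per arbor.
#' @export
summarizeCohort <- function(cohort, genotype = NULL) {
  rows <- do.call(rbind, lapply(cohort, summarizeArbor))
  rows$genotype <- if (is.null(genotype))
    vapply(cohort, function(t) t@genotype, character(1)) else genotype
  rows
}
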