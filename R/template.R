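## Skeleton templates: construction, packaged wildtype, plain-text round trip,
## and template-implied geometry (used by the generator and the matcher).

#' Build a skeleton template from a per-branch table
#'
#' @param rows data.frame with columns `id`, `parent_id` (`NA` for the root),
#'   `attach_fraction`, `dir_x`, `dir_y`, `mean_length`, `sd_length`,
#'   `presence_prob`. Directions are normalized; rows are reordered
#'   parents-before-children.
#' @param name template name.
#' @param freq_threshold presence frequency above which (strictly) a branch
#'   counts as core/skeletal.
#' @return A [SkeletonTemplate-class].
#' @examples
#' tpl <- wildtypeTemplate()
#' nrow(templateBranches(tpl))  # 16
#' @export
makeTemplate <- function(rows, name = "template", freq_threshold = 0.8) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (anyDuplicated(rows$id)) stop("template branch ids must be unique")
  known <- rows$parent_id[!is.na(rows$parent_id)]
  if (!all(known %in% rows$id))
    stop("template parent_id refers to an unknown branch id")
  if (any(rows$mean_length <= 0)) stop("mean_length must be positive")
  ## topological order (also detects cycles)
  ord <- character(0)
  remaining <- rows$id
  placed <- character(0)
  while (length(remaining)) {
    ready <- remaining[is.na(rows$parent_id[match(remaining, rows$id)]) |
                       rows$parent_id[match(remaining, rows$id)] %in% placed]
    if (!length(ready)) stop("cyclic parent references in template rows")
    ord <- c(ord, ready)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  rows <- rows[match(ord, rows$id), , drop = FALSE]
  n <- sqrt(rows$dir_x^2 + rows$dir_y^2)
  rows$dir_x <- rows$dir_x / n
  rows$dir_y <- rows$dir_y / n
  rownames(rows) <- NULL
  new("SkeletonTemplate", name = name, branches = rows,
      freqThreshold = freq_threshold)
}

#' The packaged wildtype skeleton template
#'
#' Sixteen core branches of the posterior scutellar arbor, ordered
#' parents-before-children, with mean lengths spanning 13-151 um and marginal
#' presence frequencies of 0.92-1. Per-branch length SDs default to a 20%
#' coefficient of variation (overridable via `sd_cv`). The geometry lives in a
#' 135 x 245 um field with the entry point at (20, 35) um (x medio-lateral,
#' y increasing posteriorly from the anterior ganglion margin).
#'
#' @param sd_cv per-branch length SD as a fraction of the mean.
#' @return A [SkeletonTemplate-class] with 16 branches.
#' @export
wildtypeTemplate <- function(sd_cv = 0.2) {
  rows <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
id  parent_id dir_x  dir_y  mean_length presence_prob
b01 NA         0.500  0.866  45 1.00
b02 b01       -0.122  0.993 151 1.00
b03 b01        0.906  0.423  95 1.00
b04 b02        0.993  0.122  40 0.97
b05 b02        0.766 -0.643  70 0.98
b06 b04        0.766  0.643  18 0.93
b12 b04        0.707 -0.707  15 0.94
b10 b05       -0.643 -0.766  35 0.95
b13 b05        0.259 -0.966  52 0.93
b11 b05        0.985  0.174  26 0.94
b07 b03       -0.423 -0.906  80 0.95
b08 b03       -0.174  0.985 120 0.99
b09 b08       -0.985  0.174  22 0.96
b15 b08       -0.574 -0.819  30 0.95
b14 b10        0.087  0.996  13 0.92
b16 b10        0.707 -0.707  60 0.93
")
  rows$attach_fraction <- ifelse(is.na(rows$parent_id), 0, 1)
  rows$sd_length <- sd_cv * rows$mean_length
  makeTemplate(rows, name = "pSc-wildtype")
}

## field-of-view and entry used by the packaged template (um)
.FOV <- c(135, 245)
.ENTRY <- c(20, 35)
.FOV_MARGIN <- 4

#' Template-implied geometry
#'
#' Walks the template tree and returns, for each branch, its start and end
#' position (at scale `scale`, origin at the entry point), its depth
#' (root = 0) and its unit direction.
#'
#' @param template a [SkeletonTemplate-class].
#' @param scale global length multiplier.
#' @param entry numeric (x, y) of the root start.
#' @return data.frame with columns `id`, `x0`, `y0`, `x1`, `y1`, `depth`,
#'   `dir_x`, `dir_y`.
#' @export
templateGeometry <- function(template, scale = 1, entry = .ENTRY) {
  b <- template@branches
  n <- nrow(b)
  out <- data.frame(id = b$id, x0 = NA_real_, y0 = NA_real_, x1 = NA_real_,
                    y1 = NA_real_, depth = NA_integer_,
                    dir_x = b$dir_x, dir_y = b$dir_y,
                    stringsAsFactors = FALSE)
  idx <- stats::setNames(seq_len(n), b$id)
  for (i in seq_len(n)) {
    if (is.na(b$parent_id[i])) {
      s <- entry
      out$depth[i] <- 0L
    } else {
      j <- idx[[b$parent_id[i]]]
      ## attach at attach_fraction along the parent's straight segment
      f <- b$attach_fraction[i]
      s <- c(out$x0[j] + f * (out$x1[j] - out$x0[j]),
             out$y0[j] + f * (out$y1[j] - out$y0[j]))
      out$depth[i] <- out$depth[j] + 1L
    }
    e <- s + c(b$dir_x[i], b$dir_y[i]) * b$mean_length[i] * scale
    out$x0[i] <- s[1]; out$y0[i] <- s[2]; out$x1[i] <- e[1]; out$y1[i] <- e[2]
  }
  out
}

#' Write / read a skeleton template as plain text
#'
#' Tab-separated branch table with `# key: value` header lines; the format is
#' round-trippable and shared with consensus templates built from cohorts.
#'
#' @param template a [SkeletonTemplate-class].
#' @param path file path.
#' @export
writeTemplate <- function(template, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name: %s", template@name),
               sprintf("# freq_threshold: %.6g", template@freqThreshold),
               sprintf("# converged: %s", template@converged)), con)
  utils::write.table(template@branches, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTemplate
#' @return `readTemplate()` returns the [SkeletonTemplate-class].
#' @export
readTemplate <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key, default) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  rows <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  tpl <- makeTemplate(rows, name = getv("name", "template"),
                      freq_threshold = as.numeric(getv("freq_threshold", "0.8")))
  tpl@converged <- identical(getv("converged", "TRUE"), "TRUE")
  tpl
}
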