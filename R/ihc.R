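## ROI-based semi-quantitative protein-level estimation on two-channel
## stacks: integrated target-channel intensity normalized to the structural
## counterstain, averaged over randomly placed ROIs.

#' IHC quantification parameters
#'
#' @param n_rois number of regions of interest.
#' @param roi_size (width, height) of each ROI in micrometers.
#' @param seed integer seed for ROI placement.
#' @return Named list of parameters.
#' @export
ihcParams <- function(n_rois = 4L, roi_size = c(20, 20), seed = 1L) {
  stopifnot(n_rois >= 1)
  list(n_rois = as.integer(n_rois), roi_size = roi_size,
       seed = as.integer(seed))
}

#' Measure channel-ratio ROIs on a two-channel stack
#'
#' ROIs are sampled uniformly (fixed seed) inside the bounding box of the
#' structural-channel foreground, on maximum projections; per ROI the
#' integrated channel-A intensity is normalized to the integrated channel-B
#' (structural) intensity. An ROI with zero structural signal is resampled
#' (up to 10 attempts).
#'
#' @param stack a two-channel [ImageStack-class] (channel 1 = target,
#'   channel 2 = structural).
#' @param params from [ihcParams()].
#' @return List with `rois` (data.frame: bounds in um, `integrated_a`,
#'   `integrated_b`, `ratio`), `mean_ratio`, `sd_ratio`, `resampled` (count).
#' @export
measureRois <- function(stack, params = ihcParams()) {
  if (dim(stack@voxels)[4] != 2L) stop("expected a two-channel stack")
  pa <- maxProjection(stack, 1L)
  pb <- maxProjection(stack, 2L)
  px <- stack@pixelSize
  ## foreground bounding box of the structural channel
  thr <- EBImage::otsu(EBImage::Image(pmin(pmax(pb, 0), 1)), range = c(0, 1))
  fg <- which(pb > thr, arr.ind = TRUE)
  if (!nrow(fg)) stop("structural channel has no foreground")
  bb <- rbind(apply(fg, 2, min), apply(fg, 2, max))
  wpx <- ceiling(params$roi_size[1] / px)
  hpx <- ceiling(params$roi_size[2] / px)
  xmax <- max(bb[1, 1], bb[2, 1] - wpx)
  ymax <- max(bb[1, 2], bb[2, 2] - hpx)

  set.seed(params$seed)
  rois <- NULL
  resampled <- 0L
  for (k in seq_len(params$n_rois)) {
    ok <- FALSE
    for (attempt in 1:10) {
      i0 <- if (xmax > bb[1, 1]) sample(bb[1, 1]:xmax, 1) else bb[1, 1]
      j0 <- if (ymax > bb[1, 2]) sample(bb[1, 2]:ymax, 1) else bb[1, 2]
      ii <- i0:min(nrow(pb), i0 + wpx - 1L)
      jj <- j0:min(ncol(pb), j0 + hpx - 1L)
      ia <- sum(pa[ii, jj])
      ib <- sum(pb[ii, jj])
      if (ib > 0) { ok <- TRUE; break }
      resampled <- resampled + 1L
    }
    if (!ok) stop("ROI with nonzero structural signal not found in 10 tries")
    rois <- rbind(rois, data.frame(
      x0 = (i0 - 1) * px + stack@origin[1],
      y0 = (j0 - 1) * px + stack@origin[2],
      width = params$roi_size[1], height = params$roi_size[2],
      integrated_a = ia, integrated_b = ib, ratio = ia / ib))
  }
  list(rois = rois, mean_ratio = mean(rois$ratio),
       sd_ratio = if (nrow(rois) > 1) stats::sd(rois$ratio) else 0,
       resampled = resampled)
}

#' Write an ROI report as CSV
#'
#' One row per ROI plus a summary row.
#'
#' @param measurement result of [measureRois()].
#' @param path output CSV path.
#' @export
writeIhcReport <- function(measurement, path) {
  df <- measurement$rois
  df$kind <- "roi"
  summary <- df[1, ]
  summary[1, ] <- NA
  summary$kind <- "summary"
  summary$ratio <- measurement$mean_ratio
  summary$integrated_a <- NA
  summary$integrated_b <- NA
  out <- rbind(df, summary)
  out$sd_ratio <- c(rep(NA, nrow(df)), measurement$sd_ratio)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
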