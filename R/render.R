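## Synthetic fluorescence rendering: arbors -> calibrated image stacks.
##
## The axon is drawn as a tube with Gaussian cross-section (FWHM = axon
## width) around the rasterized centerlines; varicosities are Gaussian blobs
## of their own diameter and intensity gain; slices are modulated by a
## Gaussian focal profile, blurred by a 2-D PSF, offset by a background level
## and corrupted by Poisson photon noise (variance noise_sd^2 at unit
## intensity), which keeps intensities nonnegative.

#' Rendering parameters
#'
#' @param field_of_view (x, y) extent in micrometers.
#' @param pixel_size micrometers per pixel.
#' @param n_slices number of focal planes.
#' @param axon_width tube FWHM in micrometers.
#' @param psf_sigma 2-D point-spread sigma in micrometers.
#' @param background_level additive background intensity.
#' @param noise_sd photon-noise scale: intensity variance at unit intensity
#'   (0 disables noise).
#' @param z_sigma focal-profile sigma in slices.
#' @param base_amp in-focus intensity of the axon shaft.
#' @return Named list of parameters.
#' @export
renderParams <- function(field_of_view = c(135, 245), pixel_size = 0.5,
                         n_slices = 16, axon_width = 1.5, psf_sigma = 0.6,
                         background_level = 0.05, noise_sd = 0.02,
                         z_sigma = 1.5, base_amp = 0.25) {
  stopifnot(pixel_size > 0, n_slices >= 1)
  list(field_of_view = field_of_view, pixel_size = pixel_size,
       n_slices = as.integer(n_slices), axon_width = axon_width,
       psf_sigma = psf_sigma, background_level = background_level,
       noise_sd = noise_sd, z_sigma = z_sigma, base_amp = base_amp)
}

## Poisson photon noise with variance `sd2` at unit intensity
.photonNoise <- function(img, noise_sd) {
  img <- pmax(img, 0)      # FFT blur can leave ~1e-16 ringing
  if (noise_sd <= 0) return(img)
  scale <- 1 / noise_sd^2
  arr <- stats::rpois(length(img), as.vector(img) * scale) / scale
  array(arr, dim = dim(img))
}

## rasterize polylines into a logical pixel image [nx, ny]
.rasterCurves <- function(polys, nx, ny, px, origin) {
  img <- matrix(FALSE, nx, ny)
  for (p in polys) {
    q <- resamplePolyline(p, px / 4)
    i <- round((q[, 1] - origin[1]) / px) + 1L
    j <- round((q[, 2] - origin[2]) / px) + 1L
    ok <- i >= 1 & i <= nx & j >= 1 & j <= ny
    img[cbind(i[ok], j[ok])] <- TRUE
  }
  img
}

## intensity field of a tube around the curves: distance transform of the
## rasterized centerline, Gaussian profile
.tubeField <- function(curve_img, sigma_px) {
  d <- EBImage::distmap(1 - curve_img)
  exp(-d^2 / (2 * sigma_px^2))
}

## add a Gaussian blob (peak `amp`) at (x, y) um into img (modified in place)
.addBlob <- function(img, x, y, sigma_px, amp, px, origin) {
  nx <- nrow(img); ny <- ncol(img)
  ci <- (x - origin[1]) / px + 1
  cj <- (y - origin[2]) / px + 1
  r <- ceiling(3 * sigma_px)
  ii <- max(1, floor(ci - r)):min(nx, ceiling(ci + r))
  jj <- max(1, floor(cj - r)):min(ny, ceiling(cj + r))
  if (!length(ii) || !length(jj)) return(img)
  g <- outer(exp(-(ii - ci)^2 / (2 * sigma_px^2)),
             exp(-(jj - cj)^2 / (2 * sigma_px^2)))
  img[ii, jj] <- pmax(img[ii, jj], amp * g)
  img
}

#' Render an arbor into a fluorescence image stack
#'
#' @param arbor an [ArborTree-class] (raw generator coordinates).
#' @param params from [renderParams()].
#' @return An [ImageStack-class] (one channel). The `origin` slot maps pixel
#'   (1,1) back to arbor coordinates. `degraded` is `TRUE` when
#'   `pixel_size > axon_width` (tracing not guaranteed).
#' @export
renderStack <- function(arbor, params = renderParams()) {
  px <- params$pixel_size
  polys <- lapply(arbor@branches, function(b) b@polyline)
  ## center the arbor in the field; enlarge the grid if the arbor overflows
  fov <- params$field_of_view
  if (length(polys)) {
    allxy <- do.call(rbind, polys)
    bbox <- rbind(apply(allxy, 2, min), apply(allxy, 2, max))
    span <- bbox[2, ] - bbox[1, ] + 8
    fov <- pmax(fov, span)
    origin <- (bbox[1, ] + bbox[2, ]) / 2 - fov / 2
  } else origin <- c(0, 0)
  nx <- ceiling(fov[1] / px); ny <- ceiling(fov[2] / px)

  sigma_r <- params$axon_width / 2.355 / px
  base <- matrix(0, nx, ny)
  if (length(polys)) {
    curve <- .rasterCurves(polys, nx, ny, px, origin)
    base <- params$base_amp * .tubeField(curve, sigma_r)
    for (b in arbor@branches) {
      v <- b@varicosities
      if (!nrow(v)) next
      for (k in seq_len(nrow(v))) {
        pt <- polylinePoint(b@polyline, v$arc_position[k])
        base <- .addBlob(base, pt[1], pt[2], v$diameter[k] / 2.355 / px,
                         params$base_amp * v$intensity_gain[k], px, origin)
      }
    }
  }
  nz <- params$n_slices
  z0 <- (nz + 1) / 2
  vox <- array(0, c(nx, ny, nz, 1))
  psf_px <- params$psf_sigma / px
  for (z in seq_len(nz)) {
    img <- base * exp(-(z - z0)^2 / (2 * params$z_sigma^2))
    if (psf_px > 0.3) img <- EBImage::gblur(img, sigma = psf_px)
    img <- img + params$background_level
    img <- .photonNoise(img, params$noise_sd)
    vox[, , z, 1] <- pmin(pmax(img, 0), 1)
  }
  new("ImageStack", voxels = vox, pixelSize = px, zStep = 1,
      origin = origin, degraded = px > params$axon_width)
}

#' Render a two-channel immunohistochemistry pair
#'
#' Channel B (structural counterstain) renders a fixed fiber field; channel A
#' renders punctate signal along the same fibers, scaled linearly by
#' `expression_level`. At a fixed seed the fiber geometry, the puncta
#' positions and the channel-B noise are identical across expression levels.
#'
#' @param expression_level fraction in `[0, 1]`.
#' @param params from [renderParams()].
#' @param n_fibers number of fibers in the structural channel.
#' @param seed integer seed.
#' @return A two-channel [ImageStack-class] (channel 1 = A / target protein,
#'   channel 2 = B / structural).
#' @export
renderIhcPair <- function(expression_level, params = renderParams(),
                          n_fibers = 30, seed = 1L) {
  stopifnot(expression_level >= 0, expression_level <= 1)
  set.seed(as.integer(seed))
  px <- params$pixel_size
  fov <- params$field_of_view
  nx <- ceiling(fov[1] / px); ny <- ceiling(fov[2] / px)
  origin <- c(0, 0)

  ## fiber field: random gently-curved chords across the field
  fibers <- vector("list", n_fibers)
  puncta <- NULL
  for (k in seq_len(n_fibers)) {
    th <- stats::runif(1, 0, pi)
    mid <- c(stats::runif(1, 0, fov[1]), stats::runif(1, 0, fov[2]))
    half <- stats::runif(1, 30, 90)
    d <- c(cos(th), sin(th))
    tt <- seq(-1, 1, length.out = 9)
    bow <- stats::rnorm(1, 0, 4)
    perp <- c(-d[2], d[1])
    p <- sweep(outer(tt * half, d) + outer(bow * (1 - tt^2), perp), 2, mid, "+")
    p[, 1] <- pmin(pmax(p[, 1], 0), fov[1])
    p[, 2] <- pmin(pmax(p[, 2], 0), fov[2])
    fibers[[k]] <- p
    ## puncta along the fiber: hard-core renewal, mean spacing ~5 um
    pos <- .renewalPositions(polylineLength(p), 0.2)
    if (length(pos))
      puncta <- rbind(puncta, t(vapply(pos, function(s) polylinePoint(p, s),
                                       numeric(2))))
  }
  sigma_f <- 1.2 / 2.355 / px
  curve <- .rasterCurves(fibers, nx, ny, px, origin)
  fiberField <- 0.5 * .tubeField(curve, sigma_f)

  punctaField <- matrix(0, nx, ny)
  if (!is.null(puncta))
    for (k in seq_len(nrow(puncta)))
      punctaField <- .addBlob(punctaField, puncta[k, 1], puncta[k, 2],
                              0.8 / px, 0.7, px, origin)

  nz <- params$n_slices
  z0 <- (nz + 1) / 2
  vox <- array(0, c(nx, ny, nz, 2))
  psf_px <- params$psf_sigma / px
  mkSlice <- function(field, z, bg) {
    img <- field * exp(-(z - z0)^2 / (2 * params$z_sigma^2))
    if (psf_px > 0.3) img <- EBImage::gblur(img, sigma = psf_px)
    pmax(img + bg, 0)
  }
  ## channel B first (same RNG draws independent of expression level)
  for (z in seq_len(nz))
    vox[, , z, 2] <- pmin(pmax(.photonNoise(
      mkSlice(fiberField, z, params$background_level), params$noise_sd), 0), 1)
  for (z in seq_len(nz))
    vox[, , z, 1] <- pmin(pmax(.photonNoise(
      expression_level * mkSlice(punctaField, z, 0), params$noise_sd), 0), 1)
  new("ImageStack", voxels = vox, pixelSize = px, zStep = 1, origin = origin)
}

#' Maximum-intensity projection
#'
#' @param stack an [ImageStack-class].
#' @param channel channel index.
#' @return Numeric matrix `[x, y]`: per-pixel maximum over z.
#' @export
maxProjection <- function(stack, channel = 1L) {
  v <- stack@voxels
  out <- v[, , 1, channel]
  for (z in seq_len(dim(v)[3])[-1]) out <- pmax(out, v[, , z, channel])
  out
}

#' Write / read an image stack as multi-page TIFF (+ calibration sidecar)
#'
#' One page per focal plane; for two-channel stacks all channel-1 pages come
#' first. Physical calibration and origin are stored in a JSON sidecar next
#' to the TIFF.
#'
#' @param stack an [ImageStack-class].
#' @param path output `.tif` path.
#' @return Invisibly, `path`.
#' @export
writeImageStack <- function(stack, path) {
  d <- dim(stack@voxels)
  pages <- list()
  for (ch in seq_len(d[4])) for (z in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- t(stack@voxels[, , z, ch])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pixel_size = stack@pixelSize, z_step = stack@zStep,
               n_slices = d[3], channels = d[4], origin = stack@origin)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nz <- meta$n_slices; nc <- meta$channels
  nx <- ncol(pages[[1]]); ny <- nrow(pages[[1]])
  vox <- array(0, c(nx, ny, nz, nc))
  k <- 0L
  for (ch in seq_len(nc)) for (z in seq_len(nz)) {
    k <- k + 1L
    vox[, , z, ch] <- t(pages[[k]])
  }
  new("ImageStack", voxels = vox, pixelSize = meta$pixel_size,
      zStep = meta$z_step, origin = meta$origin)
}
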