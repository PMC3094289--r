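## Small geometry and distribution helpers shared across modules.

#' Arc length of a 2-D polyline
#'
#' @param p numeric matrix with two columns (x, y in micrometers), one row per
#'   vertex, in order.
#' @return Total arc length in micrometers (0 for fewer than 2 vertices).
#' @export
polylineLength <- function(p) {
  if (is.null(p) || nrow(p) < 2L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

## unit vector; zero-safe
unitVec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) return(c(1, 0))
  v / n
}

## rotate a 2-D vector by angle (radians)
rotate2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

angleBetween <- function(u, v) {
  u <- unitVec(u); v <- unitVec(v)
  acos(max(-1, min(1, sum(u * v))))
}

#' Resample a polyline at (approximately) fixed spacing
#'
#' Linear interpolation along the arc; endpoints preserved. Used by the
#' renderer (dense rasterization) and for length-invariance checks.
#'
#' @param p two-column vertex matrix.
#' @param spacing target spacing in micrometers.
#' @return Two-column matrix of resampled vertices.
#' @export
resamplePolyline <- function(p, spacing) {
  if (nrow(p) < 2L) return(p)
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(p[1, , drop = FALSE])
  n <- max(2L, ceiling(total / spacing) + 1L)
  at <- seq(0, total, length.out = n)
  cbind(stats::approx(s, p[, 1], xout = at)$y,
        stats::approx(s, p[, 2], xout = at)$y)
}

## nearest point on a polyline to q (exact, vectorized over segments)
nearestPolylinePoint <- function(q, p) {
  n <- nrow(p)
  if (n == 1L) return(p[1, ])
  a <- p[-n, , drop = FALSE]
  b <- p[-1, , drop = FALSE]
  abx <- b[, 1] - a[, 1]; aby <- b[, 2] - a[, 2]
  len2 <- pmax(abx^2 + aby^2, .Machine$double.eps)
  t <- pmin(pmax(((q[1] - a[, 1]) * abx + (q[2] - a[, 2]) * aby) / len2, 0), 1)
  cx <- a[, 1] + t * abx; cy <- a[, 2] + t * aby
  d2 <- (q[1] - cx)^2 + (q[2] - cy)^2
  i <- which.min(d2)
  c(cx[i], cy[i])
}

## exact minimum distance from point q to a polyline (segment-wise)
pointPolylineDistance <- function(q, p) {
  sqrt(sum((q - nearestPolylinePoint(q, p))^2))
}

## point at arc position t along polyline (clamped)
polylinePoint <- function(p, t) {
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  t <- max(0, min(t, s[length(s)]))
  i <- findInterval(t, s, rightmost.closed = TRUE)
  i <- max(1L, min(i, nrow(p) - 1L))
  f <- if (seg[i] > 0) (t - s[i]) / seg[i] else 0
  p[i, ] + f * (p[i + 1L, ] - p[i, ])
}

## Moments of a normal(m, s) truncated to (0, Inf), restricted above c >= 0:
## P(T > c), E[T 1(T > c)], E[T^2 1(T > c)].  Used by the analytic calibration.
truncNormMoments <- function(m, s, c = 0) {
  stopifnot(s > 0, c >= 0)
  z <- stats::pnorm(m / s)              # mass above 0
  b <- (c - m) / s
  q <- stats::pnorm(b, lower.tail = FALSE)
  d <- stats::dnorm(b)
  list(P  = q / z,
       M1 = (m * q + s * d) / z,
       M2 = ((m^2 + s^2) * q + s * (m + c) * d) / z)
}

## draw from normal(m, s) truncated to (0, Inf) by rejection (m/s comfortably
## positive everywhere it is used)
rTruncNorm0 <- function(n, m, s) {
  out <- stats::rnorm(n, m, s)
  bad <- which(out <= 0)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- stats::rnorm(length(bad), m, s)
    bad <- bad[out[bad] <= 0]
    guard <- guard + 1L
  }
  if (length(bad)) out[bad] <- abs(out[bad]) + .Machine$double.eps
  out
}

## mean-1 gamma multiplier with coefficient of variation cv (cv = 0 -> exactly 1)
rGammaCV <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  a <- 1 / cv^2
  stats::rgamma(n, shape = a, rate = a)
}

## deterministic quadrature over the mean-1 gamma factor: E[f(g)]
gammaQuadrature <- function(cv, f, nodes = 24L) {
  if (cv <= 0) return(f(1))
  a <- 1 / cv^2
  p <- (seq_len(nodes) - 0.5) / nodes
  g <- stats::qgamma(p, shape = a, rate = a)
  mean(vapply(g, f, numeric(1)))
}
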