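## shared fixtures: tiny trees and calibrated configurations built in code

## straight single-branch tree of given arc length
straightTree <- function(len = 100, from = c(20, 40), dir = c(1, 0.4),
                         width = 135) {
  dir <- dir / sqrt(sum(dir^2))
  p <- cbind(from[1] + seq(0, len, length.out = 25) * dir[1],
             from[2] + seq(0, len, length.out = 25) * dir[2])
  br <- arborquant:::.newBranch("b01", NA_character_, p)
  new("ArborTree", entryPoint = p[1, ], ganglionWidth = width,
      branches = list(br))
}

## tiny hand-built tree: trunk + two daughters (lengths 40, 25, 22);
## daughter lengths sit comfortably above the ~1 um tracing resolution
yTree <- function(width = 135) {
  trunk <- cbind(seq(30, 30, length.out = 9), seq(30, 70, length.out = 9))
  d1 <- cbind(seq(30, 48, length.out = 7), seq(70, 86, length.out = 7))
  d1 <- d1 * (25 / arborquant::polylineLength(d1)) +
    matrix(rep(c(30, 70) * (1 - 25 / arborquant::polylineLength(d1)), each = 7), ncol = 2)
  d2 <- cbind(seq(30, 14, length.out = 7), seq(70, 84, length.out = 7))
  d2 <- d2 * (22 / arborquant::polylineLength(d2)) +
    matrix(rep(c(30, 70) * (1 - 22 / arborquant::polylineLength(d2)), each = 7), ncol = 2)
  br <- list(arborquant:::.newBranch("t", NA_character_, trunk),
             arborquant:::.newBranch("a", "t", d1),
             arborquant:::.newBranch("b", "t", d2))
  new("ArborTree", entryPoint = trunk[1, ], ganglionWidth = width,
      branches = br)
}

## a tree with explicit branch lengths and varicosity counts (straight,
## chained off a trunk) for arithmetic checks
metricTree <- function(lengths = c(10, 20), nvari = c(1, 3), width = 135) {
  trunkLen <- lengths[1]
  p1 <- cbind(rep(30, 11), seq(30, 30 + trunkLen, length.out = 11))
  vb <- function(n, len) data.frame(
    arc_position = if (n > 0) seq(1, len - 1, length.out = n) else numeric(0),
    diameter = rep(3, n), intensity_gain = rep(2.5, n))
  br <- list(arborquant:::.newBranch("b1", NA_character_, p1,
                                     varicosities = vb(nvari[1], trunkLen)))
  for (k in seq_along(lengths)[-1]) {
    start <- br[[k - 1]]@polyline[nrow(br[[k - 1]]@polyline), ]
    dir <- if (k %% 2 == 0) c(1, 0.2) else c(-0.6, 1)
    dir <- dir / sqrt(sum(dir^2))
    p <- cbind(start[1] + seq(0, lengths[k], length.out = 11) * dir[1],
               start[2] + seq(0, lengths[k], length.out = 11) * dir[2])
    br[[k]] <- arborquant:::.newBranch(paste0("b", k),
                                       paste0("b", k - 1), p,
                                       varicosities = vb(nvari[k], lengths[k]))
  }
  new("ArborTree", entryPoint = p1[1, ], ganglionWidth = width, branches = br)
}

## calibrated packaged configuration (cached per session)
.fixtureEnv <- new.env()
calibrated <- function(name = "w-") {
  key <- paste0("cfg_", name)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- calibrateConfig(packagedGenotypes()[[name]],
                                          wildtypeTemplate())
  .fixtureEnv[[key]]
}
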