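## Vectorized Zhang-Suen morphological thinning to 1-px centerlines.

## 8-neighborhoods of the interior of a padded logical matrix
.neigh <- function(m, nx, ny) {
  list(P2 = m[1:nx, 2:(ny + 1)],          # up    (j-1 in padded = up)
       P3 = m[1:nx, 3:(ny + 2)],
       P4 = m[2:(nx + 1), 3:(ny + 2)],
       P5 = m[3:(nx + 2), 3:(ny + 2)],
       P6 = m[3:(nx + 2), 2:(ny + 1)],
       P7 = m[3:(nx + 2), 1:ny],
       P8 = m[2:(nx + 1), 1:ny],
       P9 = m[1:nx, 1:ny])
}

#' Thin a binary mask to 1-pixel centerlines (Zhang-Suen)
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same size: the morphological skeleton.
#' @export
skeletonize <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  m <- matrix(FALSE, nx + 2, ny + 2)
  m[2:(nx + 1), 2:(ny + 1)] <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      X <- m[2:(nx + 1), 2:(ny + 1)]
      nb <- .neigh(m, nx, ny)
      B <- Reduce(`+`, nb)
      seqd <- nb[c("P2", "P3", "P4", "P5", "P6", "P7", "P8", "P9", "P2")]
      A <- matrix(0L, nx, ny)
      for (k in 1:8) A <- A + (!seqd[[k]] & seqd[[k + 1]])
      if (step == 1L) {
        cnd <- X & B >= 2 & B <= 6 & A == 1 &
          !(nb$P2 & nb$P4 & nb$P6) & !(nb$P4 & nb$P6 & nb$P8)
      } else {
        cnd <- X & B >= 2 & B <= 6 & A == 1 &
          !(nb$P2 & nb$P4 & nb$P8) & !(nb$P2 & nb$P6 & nb$P8)
      }
      if (any(cnd)) {
        X[cnd] <- FALSE
        m[2:(nx + 1), 2:(ny + 1)] <- X
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nx + 1), 2:(ny + 1)]
}

## 8-neighbor count of each skeleton pixel
.skelDegree <- function(skel) {
  nx <- nrow(skel); ny <- ncol(skel)
  m <- matrix(FALSE, nx + 2, ny + 2)
  m[2:(nx + 1), 2:(ny + 1)] <- skel
  Reduce(`+`, .neigh(m, nx, ny))
}

## reduced-adjacency degree: diagonal neighbors are not counted when an
## orthogonal two-step path exists (removes stair-step artifacts of thinning
## that otherwise masquerade as junctions)
.reducedDegree <- function(skel) {
  nx <- nrow(skel); ny <- ncol(skel)
  m <- matrix(FALSE, nx + 2, ny + 2)
  m[2:(nx + 1), 2:(ny + 1)] <- skel
  nb <- .neigh(m, nx, ny)
  ## orthogonal: P2 (up), P4 (right), P6 (down), P8 (left)
  deg <- nb$P2 + nb$P4 + nb$P6 + nb$P8
  deg <- deg + (nb$P3 & !(nb$P2 | nb$P4))   # up-right
  deg <- deg + (nb$P5 & !(nb$P4 | nb$P6))   # down-right
  deg <- deg + (nb$P7 & !(nb$P6 | nb$P8))   # down-left
  deg <- deg + (nb$P9 & !(nb$P8 | nb$P2))   # up-left
  deg
}

## is the diagonal step (dx, dy) from (x, y) redundant (shortcut of two
## orthogonal steps)?
.redundantDiag <- function(skel, x, y, dx, dy) {
  skel[x + dx, y] || skel[x, y + dy]
}
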