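## Minimum-cost assignment (Jonker-Volgenant shortest augmenting path).
## Used for branch correspondence; small matrices (<= ~40 x 40), pure R.

#' Solve a square minimum-cost assignment problem
#'
#' @param cost square numeric cost matrix.
#' @return Integer vector `a` with `a[i]` = column assigned to row `i`;
#'   attribute `"total"` holds the minimized total cost.
#' @export
solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  if (n == 0L) {
    out <- integer(0); attr(out, "total") <- 0; return(out)
  }
  INF <- .Machine$double.xmax / 4
  V <- n + 1L                     # virtual column
  u <- numeric(n)
  v <- numeric(V)
  p <- integer(V)                 # p[j] = row assigned to column j (0 = none)
  way <- integer(V)
  for (i in seq_len(n)) {
    p[V] <- i
    j0 <- V
    minv <- rep(INF, V)
    used <- rep(FALSE, V)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(V)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == V) break
    }
  }
  a <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) a[p[j]] <- j
  attr(a, "total") <- sum(cost[cbind(seq_len(n), a)])
  a
}

## Brute-force oracle: enumerate all row->column injections of a square
## matrix; returns the same structure as solveAssignment.  Only for tests and
## the consensus oracle (n <= 7).
bruteAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 8L)
  if (n == 0L) {
    out <- integer(0); attr(out, "total") <- 0; return(out)
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (k in seq_along(v))
      out <- c(out, lapply(perms(v[-k]), function(p) c(v[k], p)))
    out
  }
  best <- NULL; bestc <- Inf
  for (pp in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), pp)])
    if (cc < bestc - 1e-12) { bestc <- cc; best <- pp }
  }
  a <- as.integer(best)
  attr(a, "total") <- bestc
  a
}
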