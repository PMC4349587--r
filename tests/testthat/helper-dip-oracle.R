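# Exhaustive small-sample dip oracle, independent of the package's
# hull-based algorithm. For samples with at most 3 distinct values every
# mode placement (between points, outside the range, or at a point with the
# mode's jump absorbing the ECDF step) is enumerated, and each side's
# convex/concave in-tube chain is solved in closed form (sides have <= 3
# support points, so the shape constraint is a single slope inequality).
# The dip is found by bisection on the tube half-width.
dip_oracle <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  v <- unique(x)
  K <- length(v)
  stopifnot(K <= 3L)
  P <- c(0, cumsum(tabulate(match(x, v), K)) / n)
  if (K == 1L) return(1 / (2 * n))
  tol <- 1e-12

  convex_min <- function(tv, tl, tu) {
    j <- length(tv)
    tl <- pmax(tl, 0)
    if (j == 0L) return(list(ok = TRUE, cmin = 0))
    if (any(tl > tu + tol)) return(list(ok = FALSE))
    if (j == 1L) return(list(ok = TRUE, cmin = tl[1]))
    if (j == 2L) {
      if (tl[1] > tu[2] + tol) return(list(ok = FALSE))
      return(list(ok = TRUE, cmin = max(tl)))
    }
    c2 <- max(tl[1], tl[2])
    if (c2 > tu[2] + tol) return(list(ok = FALSE))
    c1 <- min(tu[1], c2)
    if (c1 < tl[1] - tol) return(list(ok = FALSE))
    dx1 <- tv[2] - tv[1]
    dx2 <- tv[3] - tv[2]
    cmin3 <- max(tl[3], c2, c2 + dx2 / dx1 * (c2 - c1))
    if (cmin3 > tu[3] + tol) return(list(ok = FALSE))
    list(ok = TRUE, cmin = cmin3)
  }

  concave_max <- function(tv, tl, tu) {
    j <- length(tv)
    tu <- pmin(tu, 1)
    if (j == 0L) return(list(ok = TRUE, dmax = 1))
    if (any(tl > tu + tol)) return(list(ok = FALSE))
    if (j == 1L) return(list(ok = TRUE, dmax = tu[1]))
    if (j == 2L) {
      if (tl[1] > tu[2] + tol) return(list(ok = FALSE))
      return(list(ok = TRUE, dmax = min(tu)))
    }
    d2 <- min(tu[2], tu[3])
    if (d2 < tl[2] - tol) return(list(ok = FALSE))
    d3 <- max(tl[3], d2)
    if (d3 > tu[3] + tol) return(list(ok = FALSE))
    dx1 <- tv[2] - tv[1]
    dx2 <- tv[3] - tv[2]
    dmax1 <- min(tu[1], d2, d2 - dx1 / dx2 * (d3 - d2))
    if (dmax1 < tl[1] - tol) return(list(ok = FALSE))
    list(ok = TRUE, dmax = dmax1)
  }

  feas <- function(eps) {
    l <- pmax(0, P[-1] - eps)
    u <- pmin(1, P[-(K + 1)] + eps)
    for (s in 0:K) {
      idxL <- seq_len(s)
      L <- convex_min(v[idxL], l[idxL], u[idxL])
      if (!L$ok) next
      idxR <- if (s < K) (s + 1):K else integer(0)
      R <- concave_max(v[idxR], l[idxR], u[idxR])
      if (!R$ok) next
      if (s == 0L || s == K) return(TRUE)
      if (L$cmin <= R$dmax + tol) return(TRUE)
    }
    for (k in 1:K) {
      idxL <- seq_len(k)
      tl <- l[idxL]; tu <- u[idxL]
      tl[k] <- max(0, P[k] - eps)      # left limit matched to the pre-jump ECDF
      L <- convex_min(v[idxL], tl, tu)
      if (!L$ok) next
      idxR <- k:K
      tl2 <- l[idxR]; tu2 <- u[idxR]
      tu2[1] <- min(1, P[k + 1] + eps) # right value matched to the post-jump ECDF
      R <- concave_max(v[idxR], tl2, tu2)
      if (!R$ok) next
      if (L$cmin <= R$dmax + tol) return(TRUE)
    }
    FALSE
  }

  lo <- 0; hi <- 0.5
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    if (feas(mid)) hi <- mid else lo <- mid
  }
  max(hi, 1 / (2 * n))
}
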