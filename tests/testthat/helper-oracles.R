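# Independent oracles used to cross-check the package implementation.
# Everything here is deliberately written on a different route than the
# code under test: even-odd containment only, adaptive bisection instead
# of analytic arc intersections, dense enumeration instead of dynamic
# programming, explicit matrix algebra instead of list-based weights.

# even-odd point-in-polygon (no boundary logic; used at arc midpoints,
# which are almost surely off the boundary)
oracle_pip <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- ring[i, 2]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- ring[i, 1] + (py - yi) * (ring[j, 1] - ring[i, 1]) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# fraction of the circle (cx, cy, r) inside `ring`, by midpoint sampling
# with bisection refinement of every indicator transition
oracle_edge_weight <- function(cx, cy, r, ring, n0 = 1024L, iters = 60L) {
  h <- 2 * pi / n0
  mids <- (seq_len(n0) - 0.5) * h
  g <- vapply(mids, function(th)
    oracle_pip(cx + r * cos(th), cy + r * sin(th), ring), logical(1))
  inside <- 0
  for (i in seq_len(n0)) {
    a <- mids[i]
    b <- if (i < n0) mids[i + 1L] else mids[1L] + 2 * pi
    ga <- g[i]
    gb <- g[if (i < n0) i + 1L else 1L]
    if (ga == gb) {
      if (ga) inside <- inside + (b - a)
    } else {
      lo <- a; hi <- b
      for (it in seq_len(iters)) {
        mid <- (lo + hi) / 2
        gm <- oracle_pip(cx + r * cos(mid), cy + r * sin(mid), ring)
        if (gm == ga) lo <- mid else hi <- mid
      }
      t <- (lo + hi) / 2
      if (ga) inside <- inside + (t - a)
      if (gb) inside <- inside + (b - t)
    }
  }
  inside / (2 * pi)
}

oracle_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# brute-force Ripley K: explicit double loop over ordered pairs with
# oracle edge weights
oracle_k <- function(x, y, ring, radii) {
  n <- length(x)
  A <- oracle_area(ring)
  d <- as.matrix(dist(cbind(x, y)))
  invw <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      invw[i, j] <- 1 / oracle_edge_weight(x[i], y[i], d[i, j], ring)
    }
  }
  # diagonal entries of invw are 0, so selecting d < t over the whole
  # matrix sums exactly the ordered pairs with d_ij < t
  vapply(radii, function(t) A / n^2 * sum(invw[d < t]), numeric(1))
}

# exhaustive search over contiguous partitions of the distinct sorted
# values into k classes; returns minimal SDCM
oracle_jenks_sdcm <- function(values, k) {
  sv <- sort(unique(values))
  w <- as.numeric(table(factor(values, levels = sv)))
  m <- length(sv)
  sse <- function(i, j) {
    ww <- w[i:j]; vv <- sv[i:j]
    mu <- sum(ww * vv) / sum(ww)
    sum(ww * (vv - mu)^2)
  }
  best <- Inf
  # compositions: choose k-1 cut points among m-1 gaps
  cuts <- utils::combn(m - 1L, k - 1L)
  if (k == 1L) return(sse(1L, m))
  for (c in seq_len(ncol(cuts))) {
    bounds <- c(0L, cuts[, c], m)
    s <- sum(vapply(seq_len(k), function(g)
      sse(bounds[g] + 1L, bounds[g + 1L]), numeric(1)))
    if (s < best) best <- s
  }
  best
}

# global Moran's I by explicit matrix algebra on a row-standardized
# weights matrix
oracle_global_moran <- function(values, Wmat) {
  z <- values - mean(values)
  n <- length(z)
  s0 <- sum(Wmat)
  (n / s0) * as.numeric(t(z) %*% Wmat %*% z) / sum(z^2)
}

# dense row-standardized queen weights matrix for an nr x nc lattice,
# built from index arithmetic (not from polygon contacts)
oracle_lattice_queen <- function(nr, nc) {
  n <- nr * nc
  Wmat <- matrix(0, n, n)
  id <- function(r, c) (r - 1L) * nc + c
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          r2 <- r + dr; c2 <- c + dc
          if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc)
            Wmat[id(r, c), id(r2, c2)] <- 1
        }
      }
    }
  }
  sweep(Wmat, 1L, rowSums(Wmat), "/")
}
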