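# Minimal planar geometry for polygonal areal units.
#
# Rings are n x 2 numeric matrices of vertices in order, WITHOUT the first
# vertex repeated at the end.  No spatial geometry package is assumed: the
# primitives here (area, centroid, containment, contiguity) are the ones the
# analysis itself is built on, and each is cross-checked in the test suite.

#' Build an axis-aligned rectangular ring
#'
#' @param x0,y0 lower-left corner.
#' @param x1,y1 upper-right corner.
#' @return A 4 x 2 matrix of vertices in counter-clockwise order.
#' @export
make_rect <- function(x0, y0, x1, y1) {
  stopifnot(x1 > x0, y1 > y0)
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

as_ring <- function(ring) {
  ring <- as.matrix(ring)
  stopifnot(is.numeric(ring), ncol(ring) == 2L, nrow(ring) >= 3L)
  # drop a duplicated closing vertex if present
  n <- nrow(ring)
  if (all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  stopifnot(nrow(ring) >= 3L)
  unname(ring)
}

#' Polygon area (shoelace formula)
#' @param ring vertex matrix, see [make_rect()].
#' @return Non-negative area.
#' @export
polygon_area <- function(ring) {
  ring <- as_ring(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  j <- c(seq_len(nrow(ring))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Polygon centroid
#' @inheritParams polygon_area
#' @return Length-2 numeric (x, y).
#' @export
polygon_centroid <- function(ring) {
  ring <- as_ring(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  j <- c(seq_len(nrow(ring))[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(abs(ring)) ^ 2)
    return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

bbox_of <- function(ring) {
  ring <- as_ring(ring)
  c(xmin = min(ring[, 1L]), ymin = min(ring[, 2L]),
    xmax = max(ring[, 1L]), ymax = max(ring[, 2L]))
}

is_axis_rect <- function(ring) {
  ring <- as_ring(ring)
  if (nrow(ring) != 4L) return(FALSE)
  xs <- sort(unique(ring[, 1L])); ys <- sort(unique(ring[, 2L]))
  length(xs) == 2L && length(ys) == 2L &&
    all(ring[, 1L] %in% xs) && all(ring[, 2L] %in% ys)
}

# squared distance from points (px, py) to segment (ax,ay)-(bx,by); vectorized
# over the points
point_segment_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return((px - ax) ^ 2 + (py - ay) ^ 2)
  t <- ((px - ax) * dx + (py - ay) * dy) / l2
  t <- pmin(1, pmax(0, t))
  (px - (ax + t * dx)) ^ 2 + (py - (ay + t * dy)) ^ 2
}

#' Point-in-polygon test
#'
#' Even-odd (crossing number) containment with an explicit boundary band.
#'
#' @param px,py point coordinates (vectorized).
#' @param ring polygon ring.
#' @param eps boundary half-width; points within `eps` of an edge are
#'   classified "boundary".  Defaults to `1e-9` times the polygon scale.
#' @return Integer vector: `1` inside, `0` on the boundary, `-1` outside.
#' @export
point_in_ring <- function(px, py, ring, eps = NULL) {
  ring <- as_ring(ring)
  if (is.null(eps)) eps <- 1e-9 * max(1, max(abs(ring)))
  n <- nrow(ring)
  j <- c(2:n, 1L)
  inside <- logical(length(px))
  on_bd <- logical(length(px))
  for (e in seq_len(n)) {
    ax <- ring[e, 1L]; ay <- ring[e, 2L]
    bx <- ring[j[e], 1L]; by <- ring[j[e], 2L]
    on_bd <- on_bd | point_segment_dist2(px, py, ax, ay, bx, by) <= eps ^ 2
    crosses <- ((ay > py) != (by > py))
    if (any(crosses)) {
      xin <- ax + (py - ay) * (bx - ax) / (by - ay)
      inside <- xor(inside, crosses & (px < xin))
    }
  }
  out <- ifelse(on_bd, 0L, ifelse(inside, 1L, -1L))
  out[is.na(px) | is.na(py)] <- -1L
  as.integer(out)
}

# minimum distance between two segments; 0 if they intersect or touch
segment_segment_dist <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  orient <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  d1 <- orient(ax, ay, bx, by, cx, cy)
  d2 <- orient(ax, ay, bx, by, dx, dy)
  d3 <- orient(cx, cy, dx, dy, ax, ay)
  d4 <- orient(cx, cy, dx, dy, bx, by)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  sqrt(min(point_segment_dist2(cx, cy, ax, ay, bx, by),
           point_segment_dist2(dx, dy, ax, ay, bx, by),
           point_segment_dist2(ax, ay, cx, cy, dx, dy),
           point_segment_dist2(bx, by, cx, cy, dx, dy)))
}

# TRUE if the two rings share at least one boundary point (within `snap`)
rings_touch <- function(r1, r2, snap = 0) {
  r1 <- as_ring(r1); r2 <- as_ring(r2)
  b1 <- bbox_of(r1); b2 <- bbox_of(r2)
  if (b1["xmin"] > b2["xmax"] + snap || b2["xmin"] > b1["xmax"] + snap ||
      b1["ymin"] > b2["ymax"] + snap || b2["ymin"] > b1["ymax"] + snap)
    return(FALSE)
  n1 <- nrow(r1); n2 <- nrow(r2)
  j1 <- c(2:n1, 1L); j2 <- c(2:n2, 1L)
  for (e1 in seq_len(n1)) {
    for (e2 in seq_len(n2)) {
      d <- segment_segment_dist(r1[e1, 1L], r1[e1, 2L], r1[j1[e1], 1L], r1[j1[e1], 2L],
                                r2[e2, 1L], r2[e2, 2L], r2[j2[e2], 1L], r2[j2[e2], 2L])
      if (d <= snap) return(TRUE)
    }
  }
  FALSE
}
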