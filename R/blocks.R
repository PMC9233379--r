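# Areal-unit container: a set of polygonal "block groups" with attributes.

#' Construct a block set
#'
#' @param df data frame with at least `block_id` (character, unique) and
#'   `adult_population` (non-negative).
#' @param geoms named list of polygon rings (see [make_rect()]), one per
#'   `block_id`.
#' @param window optional study-window ring; defaults to the bounding
#'   rectangle of all block geometries.
#' @param crs coordinate-reference tag: `list(kind = "utm", zone, north)`
#'   for projected meters, or `list(kind = "wgs84")`.
#' @return An object of class `block_set`.
#' @export
block_set <- function(df, geoms, window = NULL,
                      crs = list(kind = "utm", zone = 16L, north = TRUE)) {
  stopifnot(is.data.frame(df), all(c("block_id", "adult_population") %in% names(df)))
  df$block_id <- as.character(df$block_id)
  stopifnot(!anyDuplicated(df$block_id), all(df$adult_population >= 0))
  stopifnot(is.list(geoms), setequal(names(geoms), df$block_id))
  geoms <- lapply(geoms[df$block_id], as_ring)
  for (id in df$block_id) {
    if (polygon_area(geoms[[id]]) <= 0)
      stop("invalid geometry for block ", id)
  }
  if (is.null(window)) {
    bb <- sapply(geoms, bbox_of)
    window <- make_rect(min(bb["xmin", ]), min(bb["ymin", ]),
                        max(bb["xmax", ]), max(bb["ymax", ]))
  }
  structure(list(df = df, geoms = geoms, window = as_ring(window), crs = crs),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat("block_set:", nrow(x$df), "blocks, window area",
      format(polygon_area(x$window), big.mark = ","),
      if (identical(x$crs$kind, "utm")) "m^2" else "deg^2", "\n")
  invisible(x)
}

#' Number of blocks
#' @param blocks a `block_set`.
#' @return Integer count.
#' @export
n_blocks <- function(blocks) nrow(blocks$df)

#' Block centroids
#' @param blocks a `block_set`.
#' @return Two-column matrix, rows named by block id.
#' @export
block_centroids <- function(blocks) {
  out <- t(vapply(blocks$geoms, polygon_centroid, numeric(2)))
  colnames(out) <- c("x", "y")
  out
}

# project the geometry of a WGS84 block set to the UTM zone of its window
# centroid; returns the projected block_set
project_blocks <- function(blocks) {
  if (identical(blocks$crs$kind, "utm")) return(blocks)
  ctr <- polygon_centroid(blocks$window)
  lons <- range(vapply(blocks$geoms, function(g) range(g[, 1L]), numeric(2)))
  zones <- utm_zone(lons)
  zone <- utm_zone(ctr[1L])
  if (diff(range(zones)) > 1)
    warning("window spans more than 2 UTM zones; using zone of centroid (",
            zone, ")")
  north <- ctr[2L] >= 0
  geoms <- lapply(blocks$geoms, function(g)
    utm_forward(g[, 1L], g[, 2L], zone, north))
  win <- utm_forward(blocks$window[, 1L], blocks$window[, 2L], zone, north)
  # a projected rectangle is no longer exactly rectangular; keep the ring
  block_set(blocks$df, geoms, window = win,
            crs = list(kind = "utm", zone = zone, north = north))
}
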