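# Standard-format I/O: GeoJSON polygons (WGS84), CSV tables, and a sparse
# text form for spatial weights.

ring_to_wgs84 <- function(ring, crs) {
  if (identical(crs$kind, "wgs84")) return(ring)
  utm_inverse(ring[, 1L], ring[, 2L], crs$zone, crs$north)
}

#' Write a block set as GeoJSON (WGS84)
#'
#' Projected geometries are inverse-projected to geographic coordinates;
#' block attributes become feature properties.
#'
#' @param blocks a [block_set()].
#' @param path output file.
#' @param covariates optional covariate data frame merged into properties
#'   by `block_id`.
#' @return `path`, invisibly.
#' @export
write_blocks_geojson <- function(blocks, path, covariates = NULL) {
  stopifnot(inherits(blocks, "block_set"))
  df <- blocks$df
  if (!is.null(covariates))
    df <- merge(df, covariates, by = intersect(names(df), names(covariates)),
                sort = FALSE)
  df <- df[match(blocks$df$block_id, df$block_id), , drop = FALSE]
  feats <- lapply(seq_len(nrow(df)), function(i) {
    ring <- ring_to_wgs84(blocks$geoms[[df$block_id[i]]], blocks$crs)
    ring <- rbind(ring, ring[1L, , drop = FALSE])  # GeoJSON rings close
    props <- as.list(df[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(ring))))
  })
  win <- ring_to_wgs84(blocks$window, blocks$crs)
  # the study window travels as a GeoJSON foreign member so that a
  # rectangular window survives the projection round trip exactly
  gj <- list(type = "FeatureCollection", features = feats,
             window = list(type = "Polygon",
                           coordinates = list(unname(rbind(win, win[1L, ])))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a block set from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with `block_id` and
#' `adult_population` properties (as written by [write_blocks_geojson()]).
#'
#' @param path GeoJSON file in WGS84.
#' @return A [block_set()] with `crs$kind == "wgs84"`.
#' @export
read_blocks_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(gj$type, "FeatureCollection"))
  feats <- gj$features
  props <- lapply(feats, function(f) f$properties)
  df <- do.call(rbind, lapply(props, function(p)
    as.data.frame(p, stringsAsFactors = FALSE)))
  geoms <- lapply(feats, function(f) {
    stopifnot(identical(f$geometry$type, "Polygon"))
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                  function(v) c(v[[1L]], v[[2L]])))
    as_ring(ring)
  })
  names(geoms) <- df$block_id
  window <- NULL
  if (!is.null(gj$window)) {
    window <- as_ring(do.call(rbind, lapply(gj$window$coordinates[[1L]],
                                            function(v) c(v[[1L]], v[[2L]]))))
  }
  block_set(df, geoms, window = window, crs = list(kind = "wgs84"))
}

coord_cols <- function(crs) if (identical(crs$kind, "wgs84")) c("lon", "lat") else c("x", "y")

#' Write incident records as CSV
#'
#' Projected coordinates are converted to WGS84 (`lon`/`lat` headers);
#' missing geocodes stay missing.
#'
#' @param records incident data frame with attribute `crs`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_incidents_csv <- function(records, path) {
  crs <- attr(records, "crs")
  out <- records
  if (!identical(crs$kind, "wgs84")) {
    ll <- utm_inverse(records$x, records$y, crs$zone, crs$north)
    out$x <- ll[, 1L]; out$y <- ll[, 2L]
  }
  names(out)[match(c("x", "y"), names(out))] <- c("lon", "lat")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read incident records from CSV
#'
#' Accepts `lon`/`lat` (WGS84) or `x`/`y` (planar) coordinate headers.
#'
#' @param path CSV with columns `record_id`, coordinates, `timestamp`,
#'   `disposition`, `cancelled`.
#' @return Incident data frame with canonical columns `x`, `y` and a `crs`
#'   attribute.
#' @export
read_incidents_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(record_id = "character",
                                timestamp = "character",
                                disposition = "character"))
  if (all(c("lon", "lat") %in% names(df))) {
    names(df)[match(c("lon", "lat"), names(df))] <- c("x", "y")
    attr(df, "crs") <- list(kind = "wgs84")
  } else {
    stopifnot(all(c("x", "y") %in% names(df)))
    attr(df, "crs") <- list(kind = "planar")
  }
  df$cancelled <- as.logical(df$cancelled)
  df
}

#' Write facilities as CSV (WGS84 when projected)
#' @param facilities facility data frame with attribute `crs`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_facilities_csv <- function(facilities, path) {
  crs <- attr(facilities, "crs")
  out <- facilities
  if (!is.null(crs) && !identical(crs$kind, "wgs84")) {
    ll <- utm_inverse(facilities$x, facilities$y, crs$zone, crs$north)
    out$x <- ll[, 1L]; out$y <- ll[, 2L]
  }
  names(out)[match(c("x", "y"), names(out))] <- c("lon", "lat")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read facilities from CSV
#' @param path CSV with `facility_id`, `type`, and `lon`/`lat` or `x`/`y`.
#' @return Facility data frame with canonical `x`, `y` and `crs` attribute.
#' @export
read_facilities_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("lon", "lat") %in% names(df))) {
    names(df)[match(c("lon", "lat"), names(df))] <- c("x", "y")
    attr(df, "crs") <- list(kind = "wgs84")
  } else {
    attr(df, "crs") <- list(kind = "planar")
  }
  df
}

#' Export spatial weights in sparse text form
#'
#' One line per unit: `id: neighbor_id weight neighbor_id weight ...`.
#'
#' @param W a [queen_weights()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weights <- function(W, path) {
  stopifnot(inherits(W, "spatial_weights"))
  lines <- vapply(seq_along(W$ids), function(i) {
    nb <- W$neighbors[[i]]
    if (length(nb) == 0L) return(paste0(W$ids[i], ":"))
    paste0(W$ids[i], ": ",
           paste(W$ids[nb], format(W$weights[[i]], digits = 17),
                 collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
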