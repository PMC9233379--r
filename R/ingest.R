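# Record cleaning, block assignment, rate construction, facility access.

TEN_MILES_M <- 16093.4

#' Filter incident records under the study exclusion rules
#'
#' Reasons are applied in a fixed order so that the tally is a partition of
#' the input: missing geocode, outside the study area, unassociated
#' disposition code, cancelled call / false alarm, duplicate.  A duplicate
#' is a record with a `record_id` already seen, or the same
#' (coordinates, timestamp, disposition) triple as an earlier record that
#' survived the preceding rules; the first occurrence is kept.
#'
#' @param records data frame with columns `record_id`, `x`, `y`,
#'   `timestamp`, `disposition`, `cancelled` (coordinates `NA` when the
#'   geocode is absent).
#' @param window study-window ring; boundary points count as inside.
#' @param associated_dispositions non-empty set of study-relevant codes.
#' @return List with `retained` (the cleaned records) and `tally`, an
#'   `exclusion_tally` with one count per reason plus `retained`.
#' @export
filter_incidents <- function(records, window, associated_dispositions) {
  stopifnot(is.data.frame(records),
            all(c("record_id", "x", "y", "timestamp", "disposition",
                  "cancelled") %in% names(records)))
  if (length(associated_dispositions) == 0L)
    stop("associated_dispositions must be non-empty")
  window <- as_ring(window)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  miss <- is.na(records$x) | is.na(records$y)
  reason[miss] <- "missing_geocode"
  todo <- is.na(reason)
  if (any(todo)) {
    pos <- point_in_ring(records$x[todo], records$y[todo], window)
    reason[todo][pos < 0L] <- "outside_area"
  }
  todo <- is.na(reason)
  reason[todo & !(records$disposition %in% associated_dispositions)] <-
    "unassociated_disposition"
  todo <- is.na(reason)
  reason[todo & records$cancelled] <- "cancelled_or_false_alarm"
  todo <- is.na(reason)
  key <- paste(records$x, records$y, records$timestamp, records$disposition,
               sep = "\r")
  cand <- which(todo)
  dup <- duplicated(records$record_id[cand]) | duplicated(key[cand])
  reason[cand[dup]] <- "duplicate"
  retained <- records[is.na(reason), , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "crs") <- attr(records, "crs")
  tally <- structure(list(
    missing_geocode = sum(reason == "missing_geocode", na.rm = TRUE),
    outside_area = sum(reason == "outside_area", na.rm = TRUE),
    unassociated_disposition = sum(reason == "unassociated_disposition",
                                   na.rm = TRUE),
    cancelled_or_false_alarm = sum(reason == "cancelled_or_false_alarm",
                                   na.rm = TRUE),
    duplicate = sum(reason == "duplicate", na.rm = TRUE),
    retained = nrow(retained)), class = "exclusion_tally")
  list(retained = retained, tally = tally)
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat("exclusion tally:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Assign cleaned records to blocks
#'
#' Point-in-polygon assignment; a point on a shared boundary is assigned to
#' the containing block with the lowest `block_id` (deterministic
#' tie-break).  A record inside no block is a hard error: the containment
#' filter should have removed it.
#'
#' @param records cleaned records (see [filter_incidents()]).
#' @param blocks a [block_set()] in the same coordinate system.
#' @return Named integer vector of per-block counts (all blocks, zeros
#'   included), with the per-record assignment as attribute `block_of`.
#' @export
assign_to_blocks <- function(records, blocks) {
  stopifnot(inherits(blocks, "block_set"))
  ids <- sort(blocks$df$block_id)
  bxs <- t(vapply(blocks$geoms[ids], bbox_of, numeric(4)))
  assign <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    px <- records$x[i]; py <- records$y[i]
    cand <- which(bxs[, 1L] <= px & px <= bxs[, 3L] &
                  bxs[, 2L] <= py & py <= bxs[, 4L])
    for (k in cand) {  # ids sorted, so first hit is the lowest block_id
      if (point_in_ring(px, py, blocks$geoms[[ids[k]]]) >= 0L) {
        assign[i] <- ids[k]
        break
      }
    }
    if (is.na(assign[i]))
      stop("record ", records$record_id[i],
           " lies outside every block; filter it first")
  }
  counts <- integer(length(blocks$df$block_id))
  names(counts) <- blocks$df$block_id
  tb <- table(assign)
  counts[names(tb)] <- as.integer(tb)
  attr(counts, "block_of") <- assign
  counts
}

#' Incident rates per 1,000 adult population per year
#'
#' `rate = (count / n_years) / adult_population * 1000`.  Blocks with zero
#' adult population are excluded from the table and reported via the
#' `excluded_blocks` attribute.
#'
#' @param counts named per-block counts from [assign_to_blocks()].
#' @param blocks a [block_set()].
#' @param n_years number of years the counts span (explicit, never
#'   inferred).
#' @return Data frame `block_id`, `n_incidents`, `adult_population`,
#'   `rate`.
#' @export
compute_rates <- function(counts, blocks, n_years) {
  stopifnot(inherits(blocks, "block_set"))
  if (!is.numeric(n_years) || length(n_years) != 1L || n_years <= 0)
    stop("n_years must be a positive number")
  df <- blocks$df
  cnt <- counts[df$block_id]
  keep <- df$adult_population > 0
  out <- data.frame(block_id = df$block_id[keep],
                    n_incidents = as.integer(cnt[keep]),
                    adult_population = df$adult_population[keep],
                    rate = (cnt[keep] / n_years) / df$adult_population[keep] * 1000,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  excluded <- df$block_id[!keep]
  if (length(excluded) > 0L)
    message(length(excluded), " zero-population block(s) excluded from rates")
  attr(out, "excluded_blocks") <- excluded
  out
}

#' Distance from block centers to the nearest facility of each type
#'
#' Planar Euclidean distance from each block-polygon centroid to the
#' nearest facility of each type, in units of 10 miles (16,093.4 m).  A
#' type with no facilities yields `NA` distances and is flagged.
#'
#' @param blocks a [block_set()] in projected meters.
#' @param facilities data frame `facility_id`, `type`, `x`, `y`.
#' @param types facility types to compute; defaults to the types present.
#'   A requested type with no facilities yields `NA` distances.
#' @return Data frame with `block_id` and one `dist_<type>` column per
#'   facility type; empty types are listed in attribute `undefined_types`.
#' @export
nearest_facility_distance <- function(blocks, facilities,
                                      types = unique(facilities$type)) {
  stopifnot(inherits(blocks, "block_set"),
            all(c("type", "x", "y") %in% names(facilities)))
  ctr <- block_centroids(blocks)
  out <- data.frame(block_id = blocks$df$block_id, stringsAsFactors = FALSE)
  undefined <- character(0)
  for (tp in types) {
    fx <- facilities$x[facilities$type == tp]
    fy <- facilities$y[facilities$type == tp]
    if (length(fx) == 0L) {
      out[[paste0("dist_", tp)]] <- NA_real_
      undefined <- c(undefined, tp)
      next
    }
    d <- vapply(seq_len(nrow(ctr)), function(i)
      min(sqrt((ctr[i, 1L] - fx) ^ 2 + (ctr[i, 2L] - fy) ^ 2)), numeric(1))
    out[[paste0("dist_", tp)]] <- d / TEN_MILES_M
  }
  if (length(undefined) > 0L) {
    warning("no facilities of type: ", paste(undefined, collapse = ", "),
            "; distances undefined")
  }
  attr(out, "undefined_types") <- undefined
  out
}

#' Planar point pattern
#'
#' @param x,y projected point coordinates.
#' @param window ring containing all points (boundary allowed).
#' @param crs coordinate-reference tag.
#' @return A `point_pattern` with fields `x`, `y`, `window`, `n`, `area`.
#' @export
point_pattern <- function(x, y, window, crs = list(kind = "utm")) {
  window <- as_ring(window)
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  a <- polygon_area(window)
  stopifnot(a > 0)
  if (length(x) > 0L && any(point_in_ring(x, y, window) < 0L))
    stop("all points must lie within the window")
  structure(list(x = as.numeric(x), y = as.numeric(y), window = window,
                 n = length(x), area = a, crs = crs),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat("point_pattern:", x$n, "points, window area", format(x$area), "\n")
  invisible(x)
}

#' Project cleaned records to a planar point pattern
#'
#' Geographic (WGS84) records and window are projected to the UTM zone of
#' the window centroid; a window spanning more than two zones triggers a
#' warning and the centroid zone is used.  Records already carrying a
#' projected/planar CRS pass through unchanged.
#'
#' @param records cleaned records (no missing geocodes).
#' @param blocks a [block_set()] providing the study window.
#' @return A [point_pattern()] in meters.
#' @export
project_points <- function(records, blocks) {
  stopifnot(inherits(blocks, "block_set"))
  crs <- attr(records, "crs")
  if (is.null(crs)) crs <- blocks$crs
  if (identical(crs$kind, "wgs84")) {
    pb <- project_blocks(blocks)
    xy <- utm_forward(records$x, records$y, pb$crs$zone, pb$crs$north)
    point_pattern(xy[, 1L], xy[, 2L], pb$window, crs = pb$crs)
  } else {
    point_pattern(records$x, records$y, blocks$window, crs = crs)
  }
}
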