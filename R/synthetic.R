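# Synthetic-city generator.
#
# Emulates the shape of the study data the pipeline was designed for: a
# lattice "city" of polygonal block groups, spatially correlated
# sociodemographic covariates, an inhomogeneous incident process with a
# planted contiguous hot region, health-facility point sets, and record
# contamination (duplicates, cancelled calls, missing geocodes, out-of-area
# points) that exercises every exclusion rule in the cleaning stage.

#' Contamination specification
#'
#' Counts of contaminated records appended to the clean incident stream.
#' Each class is constructed so that the cleaning stage excludes it for
#' exactly one reason, making the exclusion tally verifiable record by
#' record.
#'
#' @param n_duplicates exact byte-identical copies of clean records.
#' @param n_cancelled records flagged as cancelled calls / false alarms.
#' @param n_missing_geocode records with absent coordinates.
#' @param n_outside_area records placed outside the study window (within one
#'   window-width of the boundary, so the containment filter is exercised
#'   non-trivially).
#' @param n_unassociated records with a disposition code outside the
#'   associated set.
#' @return A `contamination_spec` object.
#' @export
contamination_spec <- function(n_duplicates = 200L, n_cancelled = 150L,
                               n_missing_geocode = 120L,
                               n_outside_area = 110L,
                               n_unassociated = 0L) {
  out <- list(n_duplicates = as.integer(n_duplicates),
              n_cancelled = as.integer(n_cancelled),
              n_missing_geocode = as.integer(n_missing_geocode),
              n_outside_area = as.integer(n_outside_area),
              n_unassociated = as.integer(n_unassociated))
  stopifnot(all(unlist(out) >= 0L))
  structure(out, class = "contamination_spec")
}

#' Synthetic city configuration
#'
#' Defaults describe a 14 x 20 lattice of 1 km cells (280 block groups,
#' echoing the size of a mid-sized US city study area), six calendar years,
#' a base incident rate of 1 per 1,000 adult population per year, and a
#' 3 x 3 contiguous hot region at five times the base rate.  Block adult
#' populations are log-normal with median approximately 980.
#'
#' @param n_rows,n_cols lattice dimensions (n_rows * n_cols >= 4).
#' @param cell_size_m cell side length in meters.
#' @param years calendar years covered by the incident stream.
#' @param base_annual_rate incidents per 1,000 adult population per year.
#' @param hot_blocks two-column matrix of (row, col) lattice indices of the
#'   planted hot region.
#' @param hot_multiplier rate multiplier (>= 1) applied in hot blocks.
#' @param contamination a [contamination_spec()].
#' @param seed master integer seed; all generator randomness derives from it.
#' @param pop_meanlog,pop_sdlog log-normal parameters of block adult
#'   population.
#' @param covariate_effects hot-block covariate shifts: additive percentage
#'   points for `pct_male`, `pct_poverty`, `pct_bachelor`; multiplicative for
#'   `income_percap` and `crime_rate`.
#' @param associated_dispositions disposition codes treated as
#'   study-relevant.
#' @param unassociated_dispositions codes outside the associated set.
#' @param origin WGS84 (lon, lat) of the lattice south-west corner, used
#'   when exporting geographic coordinates.
#' @return A `synthetic_city_config` object.
#' @export
synthetic_city_config <- function(
    n_rows = 14L, n_cols = 20L, cell_size_m = 1000,
    years = 2015:2020,
    base_annual_rate = 1.0,
    hot_blocks = as.matrix(expand.grid(row = 4:6, col = 4:6)),
    hot_multiplier = 5,
    contamination = contamination_spec(),
    seed = 1L,
    pop_meanlog = log(980), pop_sdlog = 0.5,
    covariate_effects = list(pct_male = 5, pct_poverty = 15,
                             pct_bachelor = -10, income_percap = 0.6,
                             crime_rate = 2.5),
    associated_dispositions = c("OD-HEROIN", "OD-OPIOID", "NALOXONE-ADMIN"),
    unassociated_dispositions = c("NOT-RELATED", "TRANSPORT-OTHER"),
    origin = c(-84.71, 39.02)) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("lattice dimensions must be positive")
  if (n_rows * n_cols < 4L) stop("lattice must have at least 4 cells")
  stopifnot(cell_size_m > 0, length(years) >= 1L, base_annual_rate >= 0)
  if (hot_multiplier < 1) stop("hot_multiplier must be >= 1")
  hot_blocks <- as.matrix(hot_blocks)
  if (nrow(hot_blocks) > 0L) {
    stopifnot(ncol(hot_blocks) == 2L)
    if (any(hot_blocks[, 1L] < 1L | hot_blocks[, 1L] > n_rows |
            hot_blocks[, 2L] < 1L | hot_blocks[, 2L] > n_cols))
      stop("hot_blocks outside the lattice")
  }
  stopifnot(inherits(contamination, "contamination_spec"))
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size_m = cell_size_m,
                 years = as.integer(years),
                 base_annual_rate = base_annual_rate,
                 hot_blocks = hot_blocks, hot_multiplier = hot_multiplier,
                 contamination = contamination, seed = as.integer(seed),
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 covariate_effects = covariate_effects,
                 associated_dispositions = associated_dispositions,
                 unassociated_dispositions = unassociated_dispositions,
                 origin = origin),
            class = "synthetic_city_config")
}

block_id_of <- function(row, col) sprintf("BG-%02d-%02d", row, col)

#' Generate the lattice of block-group polygons
#'
#' Cells are axis-aligned squares in the UTM zone of the configured origin;
#' the lattice south-west corner sits at the projection of `origin`.  Adult
#' populations are drawn log-normal (seeded).
#'
#' @param config a [synthetic_city_config()].
#' @return A [block_set()] in projected (UTM meter) coordinates, with
#'   columns `block_id`, `row`, `col`, `adult_population` and a logical
#'   `hot` marker.
#' @export
generate_block_lattice <- function(config) {
  stopifnot(inherits(config, "synthetic_city_config"))
  zone <- utm_zone(config$origin[1L])
  o <- utm_forward(config$origin[1L], config$origin[2L], zone)
  grid <- expand.grid(row = seq_len(config$n_rows), col = seq_len(config$n_cols))
  grid <- grid[order(grid$row, grid$col), ]
  ids <- block_id_of(grid$row, grid$col)
  cs <- config$cell_size_m
  geoms <- lapply(seq_len(nrow(grid)), function(i) {
    x0 <- o[1L] + (grid$col[i] - 1L) * cs
    y0 <- o[2L] + (grid$row[i] - 1L) * cs
    make_rect(x0, y0, x0 + cs, y0 + cs)
  })
  names(geoms) <- ids
  pop <- with_seed(derive_seed(config$seed, "lattice"),
                   round(rlnorm(length(ids), config$pop_meanlog, config$pop_sdlog)))
  hot <- rep(FALSE, length(ids))
  if (nrow(config$hot_blocks) > 0L)
    hot[ids %in% block_id_of(config$hot_blocks[, 1L], config$hot_blocks[, 2L])] <- TRUE
  df <- data.frame(block_id = ids, row = grid$row, col = grid$col,
                   adult_population = as.numeric(pop), hot = hot,
                   stringsAsFactors = FALSE)
  window <- make_rect(o[1L], o[2L], o[1L] + config$n_cols * cs,
                      o[2L] + config$n_rows * cs)
  block_set(df, geoms, window = window,
            crs = list(kind = "utm", zone = zone, north = config$origin[2L] >= 0))
}

# one smoothing pass over the lattice queen neighborhood, used to induce
# spatial correlation in covariate fields
smooth_lattice <- function(z, row, col, passes = 2L) {
  n_rows <- max(row); n_cols <- max(col)
  idx <- matrix(NA_integer_, n_rows, n_cols)
  idx[cbind(row, col)] <- seq_along(z)
  for (p in seq_len(passes)) {
    znew <- z
    for (i in seq_along(z)) {
      rr <- max(1, row[i] - 1):min(n_rows, row[i] + 1)
      cc <- max(1, col[i] - 1):min(n_cols, col[i] + 1)
      nb <- as.vector(idx[rr, cc])
      nb <- nb[nb != i]
      znew[i] <- (z[i] + mean(z[nb])) / 2
    }
    z <- znew
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate block-level sociodemographic covariates
#'
#' Produces spatially correlated fields (iid Gaussian noise smoothed over
#' the lattice queen neighborhood) transformed to realistic marginals, then
#' shifts the hot blocks: higher percent male, percent in poverty and crime
#' rate; lower percent bachelor-or-higher and per-capita income.
#'
#' @param blocks a [block_set()] from [generate_block_lattice()].
#' @param hot_ids character ids of hot blocks (must exist in `blocks`).
#' @param seed integer seed.
#' @param effects covariate shifts, see [synthetic_city_config()].
#' @return Data frame: `block_id`, `adult_population`, `pct_male`,
#'   `pct_poverty`, `pct_bachelor`, `income_percap`, `crime_rate`.
#' @export
generate_covariates <- function(blocks, hot_ids, seed,
                                effects = list(pct_male = 5, pct_poverty = 15,
                                               pct_bachelor = -10,
                                               income_percap = 0.6,
                                               crime_rate = 2.5)) {
  stopifnot(inherits(blocks, "block_set"))
  hot_ids <- as.character(hot_ids)
  if (!all(hot_ids %in% blocks$df$block_id))
    stop("unknown block id in hot_ids: ",
         paste(setdiff(hot_ids, blocks$df$block_id), collapse = ", "))
  df <- blocks$df
  n <- nrow(df)
  with_seed(derive_seed(seed, "covariates"), {
    field <- function() smooth_lattice(rnorm(n), df$row, df$col)
    pct_male <- pmin(95, pmax(5, 48.9 + 5 * field()))
    pct_poverty <- pmin(90, pmax(0, 22 + 12 * field()))
    pct_bachelor <- pmin(95, pmax(1, 29 + 14 * field()))
    income <- exp(log(24672) + 0.4 * field())
    crime <- exp(log(7.65) + 0.6 * field())
    hot <- df$block_id %in% hot_ids
    pct_male[hot] <- pmin(95, pct_male[hot] + effects$pct_male)
    pct_poverty[hot] <- pmin(90, pct_poverty[hot] + effects$pct_poverty)
    pct_bachelor[hot] <- pmax(1, pct_bachelor[hot] + effects$pct_bachelor)
    income[hot] <- income[hot] * effects$income_percap
    crime[hot] <- crime[hot] * effects$crime_rate
    data.frame(block_id = df$block_id,
               adult_population = df$adult_population,
               pct_male = pct_male, pct_poverty = pct_poverty,
               pct_bachelor = pct_bachelor,
               income_percap = income, crime_rate = crime,
               stringsAsFactors = FALSE)
  })
}

iso_time <- function(year, frac) {
  t0 <- as.numeric(as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC"))
  t1 <- as.numeric(as.POSIXct(sprintf("%d-01-01 00:00:00", year + 1L), tz = "UTC"))
  secs <- floor(t0 + frac * (t1 - t0))
  format(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ")
}

#' Generate the contaminated incident stream
#'
#' Per block and year, an incident count is drawn Poisson with mean
#' `adult_population / 1000 * base_annual_rate * hot_multiplier(if hot)`;
#' points are placed uniformly within the block polygon.  Contamination
#' records are then appended per the configuration: exact duplicates of
#' clean records, cancelled/false-alarm records, records with missing
#' geocodes, records outside the window, and (optionally) records with an
#' unassociated disposition code.
#'
#' @param blocks a [block_set()] from [generate_block_lattice()].
#' @param covariates covariate table (unused by the count model but part of
#'   the generator contract; kept for signature stability).
#' @param config a [synthetic_city_config()].
#' @return Data frame of records (`record_id`, `x`, `y`, `timestamp`,
#'   `disposition`, `cancelled`) with the block `crs` attached as an
#'   attribute; the number of clean records is attribute `n_clean`.
#' @export
generate_incidents <- function(blocks, covariates, config) {
  stopifnot(inherits(blocks, "block_set"),
            inherits(config, "synthetic_city_config"))
  if (n_blocks(blocks) == 0L) stop("empty block set")
  df <- blocks$df
  with_seed(derive_seed(config$seed, "incidents"), {
    mult <- ifelse(df$hot, config$hot_multiplier, 1)
    lam_year <- df$adult_population / 1000 * config$base_annual_rate * mult
    rows <- list()
    for (yi in seq_along(config$years)) {
      counts <- rpois(nrow(df), lam_year)
      tot <- sum(counts)
      if (tot == 0L) next
      bidx <- rep(seq_len(nrow(df)), counts)
      xy <- t(vapply(bidx, function(b) {
        bb <- bbox_of(blocks$geoms[[b]])
        c(runif(1, bb["xmin"], bb["xmax"]), runif(1, bb["ymin"], bb["ymax"]))
      }, numeric(2)))
      rows[[yi]] <- data.frame(
        x = xy[, 1L], y = xy[, 2L],
        timestamp = iso_time(config$years[yi], runif(tot)),
        disposition = sample(config$associated_dispositions, tot, replace = TRUE),
        cancelled = FALSE, stringsAsFactors = FALSE)
    }
    clean <- do.call(rbind, rows)
    if (is.null(clean)) clean <- data.frame(x = numeric(), y = numeric(),
                                            timestamp = character(),
                                            disposition = character(),
                                            cancelled = logical())
    n_clean <- nrow(clean)
    clean <- cbind(record_id = sprintf("I%06d", seq_len(n_clean)), clean)
    ct <- config$contamination
    bb <- bbox_of(blocks$window)
    wwid <- bb["xmax"] - bb["xmin"]; whgt <- bb["ymax"] - bb["ymin"]
    rnd_inside <- function(k) cbind(runif(k, bb["xmin"], bb["xmax"]),
                                    runif(k, bb["ymin"], bb["ymax"]))
    mk <- function(k, x, y, disposition, cancelled, id0) {
      data.frame(record_id = sprintf("C%06d", id0 + seq_len(k)),
                 x = x, y = y,
                 timestamp = iso_time(sample(config$years, k, replace = TRUE),
                                      runif(k)),
                 disposition = disposition, cancelled = cancelled,
                 stringsAsFactors = FALSE)
    }
    extra <- list()
    if (ct$n_duplicates > 0L) {
      if (n_clean == 0L) stop("cannot generate duplicates of an empty stream")
      extra$dup <- clean[sample(n_clean, ct$n_duplicates, replace = TRUE), ]
    }
    if (ct$n_cancelled > 0L) {
      xy <- rnd_inside(ct$n_cancelled)
      extra$canc <- mk(ct$n_cancelled, xy[, 1L], xy[, 2L],
                       sample(config$associated_dispositions, ct$n_cancelled,
                              replace = TRUE), TRUE, 0L)
    }
    if (ct$n_missing_geocode > 0L) {
      extra$miss <- mk(ct$n_missing_geocode, NA_real_, NA_real_,
                       sample(config$associated_dispositions,
                              ct$n_missing_geocode, replace = TRUE),
                       FALSE, 10000L)
    }
    if (ct$n_outside_area > 0L) {
      # rejection from the expanded bounding box keeps points strictly
      # outside the window but within one window-width of the boundary
      k <- ct$n_outside_area
      x <- numeric(0); y <- numeric(0)
      while (length(x) < k) {
        cx <- runif(2 * k, bb["xmin"] - wwid, bb["xmax"] + wwid)
        cy <- runif(2 * k, bb["ymin"] - whgt, bb["ymax"] + whgt)
        keep <- point_in_ring(cx, cy, blocks$window) < 0L
        x <- c(x, cx[keep]); y <- c(y, cy[keep])
      }
      x <- x[seq_len(k)]; y <- y[seq_len(k)]
      extra$out <- mk(k, x, y,
                      sample(config$associated_dispositions, k, replace = TRUE),
                      FALSE, 20000L)
    }
    if (ct$n_unassociated > 0L) {
      xy <- rnd_inside(ct$n_unassociated)
      extra$unas <- mk(ct$n_unassociated, xy[, 1L], xy[, 2L],
                       sample(config$unassociated_dispositions,
                              ct$n_unassociated, replace = TRUE), FALSE, 30000L)
    }
    out <- rbind(clean, do.call(rbind, unname(extra)))
    rownames(out) <- NULL
    attr(out, "crs") <- blocks$crs
    attr(out, "n_clean") <- n_clean
    out
  })
}

#' Generate health-facility point sets
#'
#' @param window study-window ring.
#' @param counts_per_type named integer vector, e.g.
#'   `c(hospital = 6, otp = 3, buprenorphine = 12)`.
#' @param seed integer seed.
#' @param crs coordinate-reference tag to attach.
#' @return Data frame `facility_id`, `type`, `x`, `y`.
#' @export
generate_facilities <- function(window,
                                counts_per_type = c(hospital = 6L, otp = 3L,
                                                    buprenorphine = 12L),
                                seed = 1L,
                                crs = list(kind = "utm", zone = 16L, north = TRUE)) {
  window <- as_ring(window)
  stopifnot(length(names(counts_per_type)) == length(counts_per_type))
  bb <- bbox_of(window)
  with_seed(derive_seed(seed, "facilities"), {
    rows <- lapply(names(counts_per_type), function(tp) {
      k <- as.integer(counts_per_type[[tp]])
      if (k == 0L)
        return(data.frame(facility_id = character(), type = character(),
                          x = numeric(), y = numeric(),
                          stringsAsFactors = FALSE))
      # rejection sampling keeps the generator valid for non-rectangular windows
      xs <- numeric(0); ys <- numeric(0)
      while (length(xs) < k) {
        cx <- runif(2 * k, bb["xmin"], bb["xmax"])
        cy <- runif(2 * k, bb["ymin"], bb["ymax"])
        keep <- point_in_ring(cx, cy, window) >= 0L
        xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
      }
      data.frame(facility_id = sprintf("%s-%03d", toupper(tp), seq_len(k)),
                 type = tp, x = xs[seq_len(k)], y = ys[seq_len(k)],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "crs") <- crs
    out
  })
}

#' Generate a full synthetic city
#'
#' Convenience wrapper running [generate_block_lattice()],
#' [generate_covariates()], [generate_incidents()] and
#' [generate_facilities()] under one configuration.
#'
#' @param config a [synthetic_city_config()].
#' @param facility_counts passed to [generate_facilities()].
#' @return List with elements `blocks`, `covariates`, `incidents`,
#'   `facilities`, `config`.
#' @export
generate_synthetic_city <- function(config = synthetic_city_config(),
                                    facility_counts = c(hospital = 6L,
                                                        otp = 3L,
                                                        buprenorphine = 12L)) {
  blocks <- generate_block_lattice(config)
  hot_ids <- blocks$df$block_id[blocks$df$hot]
  covariates <- generate_covariates(blocks, hot_ids, config$seed,
                                    config$covariate_effects)
  incidents <- generate_incidents(blocks, covariates, config)
  facilities <- generate_facilities(blocks$window, facility_counts,
                                    seed = config$seed, crs = blocks$crs)
  list(blocks = blocks, covariates = covariates, incidents = incidents,
       facilities = facilities, config = config)
}
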