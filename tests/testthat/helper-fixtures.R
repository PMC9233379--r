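# Shared fixtures, all built in code at test time.

# small block lattice with unit populations, planar coordinates
lattice_blocks <- function(nr, nc, cell = 1, pop = 1000) {
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  grid <- grid[order(grid$row, grid$col), ]
  ids <- sprintf("T-%02d-%02d", grid$row, grid$col)
  geoms <- lapply(seq_len(nrow(grid)), function(i)
    make_rect((grid$col[i] - 1) * cell, (grid$row[i] - 1) * cell,
              grid$col[i] * cell, grid$row[i] * cell))
  names(geoms) <- ids
  block_set(data.frame(block_id = ids, row = grid$row, col = grid$col,
                       adult_population = pop, stringsAsFactors = FALSE),
            geoms, crs = list(kind = "planar"))
}

# path graph weights over 4 units (row-standardized), as in the worked
# local-Moran example
path4_weights <- function() {
  structure(list(ids = c("u1", "u2", "u3", "u4"),
                 neighbors = list(2L, c(1L, 3L), c(2L, 4L), 3L),
                 weights = list(1, c(0.5, 0.5), c(0.5, 0.5), 1),
                 islands = character(0), row_standardized = TRUE),
            class = "spatial_weights")
}

# the 10-record contaminated fixture: 1 missing geocode, 1 outside the
# window, 1 unassociated code, 1 cancelled, 2 exact duplicates of
# retained records, 5 clean
fixture_records <- function() {
  clean <- data.frame(
    record_id = sprintf("R%02d", 1:5),
    x = c(0.2, 0.4, 0.6, 0.8, 0.5),
    y = c(0.2, 0.4, 0.6, 0.8, 0.3),
    timestamp = sprintf("2017-01-0%dT00:00:00Z", 1:5),
    disposition = "OD", cancelled = FALSE, stringsAsFactors = FALSE)
  bad <- data.frame(
    record_id = c("R06", "R07", "R08", "R09", "R01", "R11"),
    x = c(NA, 5.0, 0.3, 0.7, 0.2, 0.4),
    y = c(NA, 5.0, 0.3, 0.7, 0.2, 0.4),
    timestamp = c("2017-02-01T00:00:00Z", "2017-02-02T00:00:00Z",
                  "2017-02-03T00:00:00Z", "2017-02-04T00:00:00Z",
                  "2017-01-01T00:00:00Z", "2017-01-02T00:00:00Z"),
    disposition = c("OD", "OD", "OTHER", "OD", "OD", "OD"),
    cancelled = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  out <- rbind(clean, bad)
  attr(out, "crs") <- list(kind = "planar")
  out
}

# reduced synthetic city for fast tests
small_city_config <- function(seed = 7L, ...) {
  synthetic_city_config(
    n_rows = 6L, n_cols = 8L, cell_size_m = 1000,
    years = 2018:2019, base_annual_rate = 2,
    hot_blocks = as.matrix(expand.grid(row = 2:3, col = 2:3)),
    hot_multiplier = 6,
    contamination = contamination_spec(10L, 8L, 6L, 5L, 4L),
    seed = seed, ...)
}
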