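test_that("the 10-record fixture is partitioned exactly", {
  win <- make_rect(0, 0, 1, 1)
  out <- filter_incidents(fixture_records(), win, "OD")
  expect_identical(out$tally$missing_geocode, 1L)
  expect_identical(out$tally$outside_area, 1L)
  expect_identical(out$tally$unassociated_disposition, 1L)
  expect_identical(out$tally$cancelled_or_false_alarm, 1L)
  expect_identical(out$tally$duplicate, 2L)
  expect_identical(out$tally$retained, 5L)
  expect_identical(out$retained$record_id, sprintf("R%02d", 1:5))
})

test_that("exclusion reasons are applied in the fixed order", {
  win <- make_rect(0, 0, 1, 1)
  # a record failing several rules counts under the first applicable one
  rec <- data.frame(record_id = c("a", "b"),
                    x = c(NA, 5), y = c(NA, 5),
                    timestamp = c("t1", "t2"),
                    disposition = c("OTHER", "OTHER"),
                    cancelled = c(TRUE, TRUE), stringsAsFactors = FALSE)
  out <- filter_incidents(rec, win, "OD")
  expect_identical(out$tally$missing_geocode, 1L)   # not unassociated/cancelled
  expect_identical(out$tally$outside_area, 1L)
  expect_identical(out$tally$unassociated_disposition, 0L)
  expect_identical(out$tally$cancelled_or_false_alarm, 0L)
})

test_that("filtering is idempotent and all-clean input is untouched", {
  win <- make_rect(0, 0, 1, 1)
  once <- filter_incidents(fixture_records(), win, "OD")
  twice <- filter_incidents(once$retained, win, "OD")
  expect_identical(twice$retained, once$retained)
  expect_identical(sum(unlist(twice$tally[1:5])), 0L)
  expect_error(filter_incidents(fixture_records(), win, character(0)),
               "non-empty")
})

test_that("tally conservation holds for random contamination configs", {
  for (seed in 1:5) {
    set.seed(seed)
    cfg <- small_city_config(seed = seed)
    cfg$contamination <- do.call(contamination_spec,
                                 as.list(sample(0:15, 5, replace = TRUE)))
    city <- generate_synthetic_city(cfg)
    out <- filter_incidents(city$incidents, city$blocks$window,
                            cfg$associated_dispositions)
    expect_identical(out$tally$retained + sum(unlist(out$tally[1:5])),
                     nrow(city$incidents))
    # generated contamination classes are recovered exactly
    ct <- cfg$contamination
    expect_identical(out$tally$missing_geocode, ct$n_missing_geocode)
    expect_identical(out$tally$outside_area, ct$n_outside_area)
    expect_identical(out$tally$cancelled_or_false_alarm, ct$n_cancelled)
    expect_identical(out$tally$duplicate, ct$n_duplicates)
    expect_identical(out$tally$unassociated_disposition, ct$n_unassociated)
  }
})

test_that("the study-scale attrition arithmetic reproduces 10,917 -> 8,767", {
  # synthetic input built to the motivating study's totals: 8,767 clean
  # records plus 2,150 contaminated ones
  win <- make_rect(0, 0, 100, 100)
  n_clean <- 8767L
  g <- expand.grid(x = seq(0.5, 99.5, length.out = 94),
                   y = seq(0.5, 99.5, length.out = 94))[seq_len(n_clean), ]
  clean <- data.frame(record_id = sprintf("c%05d", seq_len(n_clean)),
                      x = g$x, y = g$y,
                      timestamp = sprintf("2017-01-01T%02d:%02d:00Z",
                                          seq_len(n_clean) %% 24,
                                          seq_len(n_clean) %% 60),
                      disposition = "OD", cancelled = FALSE,
                      stringsAsFactors = FALSE)
  mkbad <- function(k, prefix, ...) {
    args <- list(...)
    data.frame(record_id = sprintf("%s%05d", prefix, seq_len(k)),
               x = args$x, y = args$y, timestamp = "2017-06-01T00:00:00Z",
               disposition = args$disposition, cancelled = args$cancelled,
               stringsAsFactors = FALSE)
  }
  bad <- rbind(
    clean[rep(1:550, length.out = 550), ],                       # duplicates
    mkbad(550, "k", x = 1, y = 1, disposition = "OD", cancelled = TRUE),
    mkbad(525, "m", x = NA_real_, y = NA_real_, disposition = "OD",
          cancelled = FALSE),
    mkbad(525, "o", x = 500, y = 500, disposition = "OD", cancelled = FALSE))
  recs <- rbind(clean, bad)
  expect_identical(nrow(recs), 10917L)
  out <- filter_incidents(recs, win, "OD")
  expect_identical(out$tally$retained, 8767L)
  expect_identical(sum(unlist(out$tally[1:5])), 2150L)
})

test_that("block assignment counts, tie-breaks and errors behave", {
  blocks <- lattice_blocks(2, 2)
  rec <- data.frame(record_id = c("in", "corner"),
                    x = c(0.5, 1), y = c(0.5, 1),
                    timestamp = "t", disposition = "OD", cancelled = FALSE,
                    stringsAsFactors = FALSE)
  counts <- assign_to_blocks(rec, blocks)
  expect_identical(sum(counts), 2L)
  expect_identical(unname(counts["T-01-01"]), 2L)  # shared corner: lowest id
  bad <- data.frame(record_id = "out", x = 9, y = 9, timestamp = "t",
                    disposition = "OD", cancelled = FALSE)
  expect_error(assign_to_blocks(bad, blocks), "outside every block")

  set.seed(4)
  sc <- data.frame(record_id = sprintf("s%d", 1:200),
                   x = runif(200, 0, 2), y = runif(200, 0, 2),
                   timestamp = "t", disposition = "OD", cancelled = FALSE,
                   stringsAsFactors = FALSE)
  cnt <- assign_to_blocks(sc, blocks)
  expect_identical(sum(cnt), 200L)
  # direct-counting oracle per cell interior
  expect_identical(unname(cnt["T-02-02"]),
                   sum(sc$x > 1 & sc$y > 1))
})

test_that("rates follow the arithmetic identity and equivariances", {
  blocks <- lattice_blocks(1, 2, pop = 2000)
  counts <- c("T-01-01" = 12L, "T-01-02" = 0L)
  rt <- compute_rates(counts, blocks, n_years = 6)
  expect_equal(rt$rate, c(1.0, 0))
  expect_error(compute_rates(counts, blocks, 0), "positive")
  # doubling every population halves every rate
  blocks2 <- lattice_blocks(1, 2, pop = 4000)
  rt2 <- compute_rates(counts, blocks2, n_years = 6)
  expect_equal(rt2$rate, rt$rate / 2)
  # zero-population blocks are excluded and reported
  bz <- lattice_blocks(1, 2, pop = 0)
  bz$df$adult_population <- c(1000, 0)
  expect_message(rz <- compute_rates(counts, bz, 6), "zero-population")
  expect_identical(rz$block_id, "T-01-01")
  expect_identical(attr(rz, "excluded_blocks"), "T-01-02")
})

test_that("median block rate recovers the generating rate", {
  cfg <- synthetic_city_config(
    n_rows = 10L, n_cols = 10L, years = 2015:2020, base_annual_rate = 3,
    hot_blocks = matrix(numeric(0), 0, 2), hot_multiplier = 1,
    contamination = contamination_spec(0L, 0L, 0L, 0L, 0L), seed = 9L)
  city <- generate_synthetic_city(cfg)
  counts <- assign_to_blocks(city$incidents, city$blocks)
  rt <- compute_rates(counts, city$blocks, length(cfg$years))
  # per-block Poisson mean ~ 18; median rate within simulation error
  expect_lt(abs(median(rt$rate) - 3), 0.5)
})

test_that("nearest-facility distances match units and a brute-force scan", {
  blocks <- lattice_blocks(2, 2, cell = 10000)
  ctr <- block_centroids(blocks)
  fac <- data.frame(facility_id = "h1", type = "hospital",
                    x = ctr[1, 1], y = ctr[1, 2], stringsAsFactors = FALSE)
  d <- nearest_facility_distance(blocks, fac)
  expect_equal(d$dist_hospital[1], 0)
  fac2 <- data.frame(facility_id = "h1", type = "hospital",
                     x = ctr[1, 1] + 16093.4, y = ctr[1, 2],
                     stringsAsFactors = FALSE)
  expect_equal(nearest_facility_distance(blocks, fac2)$dist_hospital[1], 1.0)
  set.seed(8)
  fac5 <- data.frame(facility_id = sprintf("f%d", 1:5), type = "otp",
                     x = runif(5, 0, 20000), y = runif(5, 0, 20000),
                     stringsAsFactors = FALSE)
  d5 <- nearest_facility_distance(blocks, fac5)
  brute <- vapply(seq_len(nrow(ctr)), function(i)
    min(vapply(1:5, function(j)
      sqrt((ctr[i, 1] - fac5$x[j])^2 + (ctr[i, 2] - fac5$y[j])^2),
      numeric(1))) / 16093.4, numeric(1))
  expect_equal(d5$dist_otp, brute)
  # a requested type with no facilities is undefined and flagged
  expect_warning(
    dm <- nearest_facility_distance(blocks, fac5,
                                    types = c("otp", "hospital")),
    "no facilities of type")
  expect_true(all(is.na(dm$dist_hospital)))
  expect_identical(attr(dm, "undefined_types"), "hospital")
})

test_that("point_pattern validates containment and area", {
  win <- make_rect(0, 0, 1, 1)
  expect_error(point_pattern(2, 2, win), "within the window")
  pp <- point_pattern(c(0.5, 1), c(0.5, 1), win)  # boundary allowed
  expect_identical(pp$n, 2L)
  expect_equal(pp$area, 1)
})
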