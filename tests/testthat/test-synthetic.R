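test_that("configuration invariants are enforced", {
  expect_error(synthetic_city_config(n_rows = 0), "positive")
  expect_error(synthetic_city_config(n_rows = 1, n_cols = 2), "at least 4")
  expect_error(synthetic_city_config(hot_multiplier = 0.5), ">= 1")
  expect_error(synthetic_city_config(hot_blocks = cbind(99, 1)), "outside")
  expect_error(contamination_spec(n_duplicates = -1))
})

test_that("lattice geometry is forced by the tiling", {
  cfg <- synthetic_city_config(n_rows = 2L, n_cols = 2L, cell_size_m = 1000,
                               hot_blocks = matrix(numeric(0), 0, 2))
  b <- generate_block_lattice(cfg)
  expect_identical(n_blocks(b), 4L)
  expect_equal(polygon_area(b$window), 4e6)
  expect_equal(unname(vapply(b$geoms, polygon_area, numeric(1))),
               rep(1e6, 4), tolerance = 1e-9)
  # the study-scale lattice has 280 areal units
  b280 <- generate_block_lattice(synthetic_city_config())
  expect_identical(n_blocks(b280), 280L)
})

test_that("the generator is deterministic given config and seed", {
  cfg <- small_city_config(seed = 13L)
  a <- generate_synthetic_city(cfg)
  b <- generate_synthetic_city(cfg)
  expect_identical(a$blocks$df, b$blocks$df)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$incidents, b$incidents)
  expect_identical(a$facilities, b$facilities)
  c_ <- generate_synthetic_city(small_city_config(seed = 14L))
  expect_false(identical(a$incidents, c_$incidents))
})

test_that("contamination accounting is exact", {
  cfg <- small_city_config(seed = 5L)
  city <- generate_synthetic_city(cfg)
  inc <- city$incidents
  ct <- cfg$contamination
  n_clean <- attr(inc, "n_clean")
  expect_identical(nrow(inc), n_clean + ct$n_duplicates + ct$n_cancelled +
                     ct$n_missing_geocode + ct$n_outside_area +
                     ct$n_unassociated)
  # duplicates are byte-identical copies of earlier records
  key <- apply(inc, 1, paste, collapse = "\r")
  expect_identical(sum(duplicated(key)), ct$n_duplicates)
  expect_identical(sum(inc$cancelled), ct$n_cancelled)
  expect_identical(sum(is.na(inc$x)), ct$n_missing_geocode)
  geocoded <- inc[!is.na(inc$x), ]
  outside <- point_in_ring(geocoded$x, geocoded$y, city$blocks$window) < 0L
  expect_identical(sum(outside), ct$n_outside_area)
  expect_identical(sum(!inc$disposition %in% cfg$associated_dispositions),
                   ct$n_unassociated)
})

test_that("zero covariate effects leave hot blocks identical in law", {
  blocks <- generate_block_lattice(small_city_config(seed = 3L))
  hot_ids <- blocks$df$block_id[blocks$df$hot]
  null_eff <- list(pct_male = 0, pct_poverty = 0, pct_bachelor = 0,
                   income_percap = 1, crime_rate = 1)
  a <- generate_covariates(blocks, hot_ids, seed = 3L, effects = null_eff)
  b <- generate_covariates(blocks, character(0), seed = 3L,
                           effects = null_eff)
  expect_identical(a, b)
})

test_that("default effects shift hot-block covariates in direction", {
  blocks <- generate_block_lattice(synthetic_city_config(seed = 21L))
  hot_ids <- blocks$df$block_id[blocks$df$hot]
  cov <- generate_covariates(blocks, hot_ids, seed = 21L)
  hot <- cov$block_id %in% hot_ids
  # strong multiplicative effects are visible in the medians directly
  expect_lt(median(cov$income_percap[hot]), median(cov$income_percap[!hot]))
  expect_gt(median(cov$crime_rate[hot]), median(cov$crime_rate[!hot]))
  # additive effects verified mechanistically: with the same seed, the
  # difference to the null-effect table is exactly the configured shift
  # wherever clipping does not bite
  null_eff <- list(pct_male = 0, pct_poverty = 0, pct_bachelor = 0,
                   income_percap = 1, crime_rate = 1)
  cov0 <- generate_covariates(blocks, hot_ids, seed = 21L,
                              effects = null_eff)
  d_pov <- cov$pct_poverty - cov0$pct_poverty
  d_bach <- cov$pct_bachelor - cov0$pct_bachelor
  expect_true(all(d_pov[!hot] == 0) && all(d_bach[!hot] == 0))
  unclipped <- hot & cov$pct_poverty < 90 & cov$pct_bachelor > 1
  expect_equal(d_pov[unclipped], rep(15, sum(unclipped)))
  expect_equal(d_bach[unclipped], rep(-10, sum(unclipped)))
  expect_error(generate_covariates(blocks, "no-such-id", seed = 1L),
               "unknown block id")
})

test_that("clean incident totals match the analytic Poisson mean", {
  cfg <- synthetic_city_config(
    n_rows = 6L, n_cols = 8L, years = 2015:2020, base_annual_rate = 2,
    hot_blocks = matrix(numeric(0), 0, 2), hot_multiplier = 1,
    contamination = contamination_spec(0L, 0L, 0L, 0L, 0L), seed = 17L)
  blocks <- generate_block_lattice(cfg)
  cov <- generate_covariates(blocks, character(0), cfg$seed)
  inc <- generate_incidents(blocks, cov, cfg)
  mu <- sum(blocks$df$adult_population) / 1000 * cfg$base_annual_rate *
    length(cfg$years)
  expect_lt(abs(nrow(inc) - mu), 4 * sqrt(mu))
  # all points fall inside the window
  expect_true(all(point_in_ring(inc$x, inc$y, blocks$window) >= 0L))
})

test_that("facility generation partitions into the requested types", {
  win <- make_rect(0, 0, 10, 10)
  f <- generate_facilities(win, c(hospital = 4L, otp = 0L, clinic = 2L),
                           seed = 2L)
  expect_identical(as.integer(table(factor(f$type,
                                           c("hospital", "otp", "clinic")))),
                   c(4L, 0L, 2L))
  expect_true(all(point_in_ring(f$x, f$y, win) >= 0L))
  expect_identical(f, generate_facilities(win, c(hospital = 4L, otp = 0L,
                                                 clinic = 2L), seed = 2L))
})
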