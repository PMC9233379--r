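test_that("median_split follows the tie-to-low rule", {
  expect_identical(unname(median_split(c(1, 2, 3))), c("low", "low", "high"))
  expect_warning(s <- median_split(c(5, 5, 5)), "degenerate")
  expect_identical(unname(s), rep("low", 3))
  expect_error(median_split(numeric(0)), "empty")
  # invariant to monotone transforms
  set.seed(2)
  v <- rlnorm(21)
  expect_identical(median_split(v), median_split(log(v)))
})

test_that("conditional tables count and condition correctly", {
  # 10 HH units: 7 in low-A, 8 in high-B; plus 10 NS units
  categories <- stats::setNames(rep(c("HH", "NS"), each = 10),
                                sprintf("b%02d", 1:20))
  la <- stats::setNames(c(rep("low", 7), rep("high", 3),
                          rep("low", 5), rep("high", 5)), names(categories))
  lb <- stats::setNames(c(rep("high", 8), rep("low", 2),
                          rep("high", 5), rep("low", 5)), names(categories))
  tb <- conditional_cluster_table(categories, la, lb, c("A", "B"))
  expect_equal(tb$hot_fractions[[1]][["low"]], 0.7)
  expect_equal(tb$hot_fractions[[2]][["high"]], 0.8)
  expect_identical(tb$n_hot, 10L)
  # every unit appears in exactly one quadrant
  expect_identical(sum(unlist(tb$counts[c("HH", "LL", "LH", "HL", "NS")])),
                   20L)
  # fractions over the two levels of one variable sum to 1
  expect_equal(sum(tb$hot_fractions[[1]]), 1)
  # no hot spots: flagged undefined
  tb0 <- conditional_cluster_table(stats::setNames(rep("NS", 4), letters[1:4]),
                                   stats::setNames(rep(c("low", "high"), 2),
                                                   letters[1:4]),
                                   stats::setNames(rep("low", 4),
                                                   letters[1:4]))
  expect_false(tb0$defined)
  expect_true(anyNA(tb0$hot_fractions[[1]]))
  expect_error(conditional_cluster_table(categories, la[1:5], lb), "mismatch")
})

test_that("the 0.6 screen retains and rejects per the strict rule", {
  mk <- function(fa, fb) {
    structure(list(pair = c("A", "B"),
                   hot_fractions = list(c(low = fa, high = 1 - fa),
                                        c(low = 1 - fb, high = fb)),
                   n_hot = 10L), class = "conditional_table")
  }
  ret <- screen_pairs(list(mk(0.7, 0.8), mk(0.7, 0.5)), threshold = 0.6)
  expect_identical(attr(ret, "retained_flags"), c(TRUE, FALSE))
  expect_length(ret, 1L)
  # strictly-greater: 0.6 itself is rejected
  expect_identical(attr(screen_pairs(list(mk(0.6, 0.9)), 0.6),
                        "retained_flags"), FALSE)
  # raising the threshold never adds retained pairs
  tabs <- list(mk(0.7, 0.8), mk(0.65, 0.62), mk(0.9, 0.95))
  for (th in c(0.5, 0.6, 0.7, 0.9)) {
    lo <- attr(screen_pairs(tabs, th), "retained_flags")
    hi <- attr(screen_pairs(tabs, th + 0.05), "retained_flags")
    expect_true(all(hi <= lo))
  }
})

test_that("spot profiles capture planted covariate shifts", {
  # full-size city: the 9-block hot region gives stable hot medians
  blocks <- generate_block_lattice(synthetic_city_config(seed = 5L))
  hot_ids <- blocks$df$block_id[blocks$df$hot]
  covariates <- generate_covariates(blocks, hot_ids, seed = 5L)
  city <- list(blocks = blocks, covariates = covariates)
  categories <- stats::setNames(
    ifelse(city$covariates$block_id %in% hot_ids, "HH", "LL"),
    city$covariates$block_id)
  prof <- spot_profile(categories, city$covariates)
  inc <- prof[prof$variable == "income_percap", ]
  crm <- prof[prof$variable == "crime_rate", ]
  expect_lt(inc$median_hot, inc$median_all)
  expect_gt(crm$median_hot, crm$median_all)
  # single HH unit: its values are the hot medians
  one <- categories
  one[] <- "NS"; one[hot_ids[1]] <- "HH"
  p1 <- spot_profile(one, city$covariates)
  expect_equal(p1$median_hot[p1$variable == "crime_rate"],
               city$covariates$crime_rate[city$covariates$block_id ==
                                            hot_ids[1]])
  # invariant under block reordering
  perm <- sample(length(categories))
  expect_equal(spot_profile(categories[perm], city$covariates), prof)
})

test_that("facility conditionals count the shorter-distance stratum", {
  ids <- sprintf("b%d", 1:8)
  fd <- data.frame(block_id = ids,
                   dist_otp = c(0.1, 0.2, 0.3, 0.4, 1, 2, 3, 4),
                   dist_hosp = c(4, 3, 2, 1, 0.4, 0.3, 0.2, 0.1))
  categories <- stats::setNames(c("HH", "HH", "HH", "HH",
                                  "NS", "NS", "NS", "NS"), ids)
  fc <- facility_conditional(categories, fd)
  expect_equal(fc$frac_shorter[fc$type == "otp"], 1.0)
  expect_equal(fc$frac_shorter[fc$type == "hosp"], 0.0)
  # zero hot spots: undefined
  none <- stats::setNames(rep("NS", 8), ids)
  expect_true(all(is.na(facility_conditional(none, fd)$frac_shorter)))
  # undefined distances excluded with a warning
  fd$dist_otp[1] <- NA
  expect_warning(facility_conditional(categories, fd), "undefined distance")
})

test_that("facilities placed inside the hot region skew the fractions", {
  cfg <- small_city_config(seed = 23L)
  blocks <- generate_block_lattice(cfg)
  hot_ids <- blocks$df$block_id[blocks$df$hot]
  ctr <- block_centroids(blocks)
  fac <- data.frame(facility_id = sprintf("f%d", seq_along(hot_ids)),
                    type = "otp",
                    x = ctr[hot_ids, 1], y = ctr[hot_ids, 2],
                    stringsAsFactors = FALSE)
  fd <- nearest_facility_distance(blocks, fac)
  categories <- stats::setNames(
    ifelse(blocks$df$block_id %in% hot_ids, "HH", "NS"),
    blocks$df$block_id)
  fc <- facility_conditional(categories, fd)
  expect_gt(fc$frac_shorter, 0.5)
})
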