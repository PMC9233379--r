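test_that("queen contiguity on a lattice has the forced neighbor counts", {
  blocks <- lattice_blocks(3, 3)
  W <- queen_weights(blocks)
  deg <- lengths(W$neighbors)
  names(deg) <- W$ids
  expect_identical(unname(deg["T-02-02"]), 8L)  # center
  expect_identical(unname(deg["T-01-01"]), 3L)  # corner
  expect_identical(unname(deg["T-01-02"]), 5L)  # edge
  expect_equal(unique(unlist(lapply(W$weights, sum))), 1)
  # symmetry of the neighbor relation
  for (i in seq_along(W$ids))
    for (j in W$neighbors[[i]])
      expect_true(i %in% W$neighbors[[j]])
  expect_identical(W$islands, character(0))
})

test_that("disjoint polygons are islands", {
  geoms <- list(a = make_rect(0, 0, 1, 1), b = make_rect(5, 5, 6, 6))
  blocks <- block_set(data.frame(block_id = c("a", "b"),
                                 adult_population = 1), geoms)
  W <- queen_weights(blocks)
  expect_identical(sort(W$islands), c("a", "b"))
})

test_that("the path-of-4 worked example is exact", {
  W <- path4_weights()
  v <- c(u1 = 0, u2 = 0, u3 = 0, u4 = 4)
  lm <- local_moran(v, W)
  expect_equal(lm$z, c(-1, -1, -1, 3))
  expect_equal(attr(lm, "m2"), 3)
  expect_equal(lm$I, c(1 / 3, 1 / 3, -1 / 3, -1))
  expect_equal(mean(lm$I), global_moran(v, W))
  expect_equal(global_moran(v, W), -1 / 6)
})

test_that("constant values give I = 0 and NA pseudo p-values", {
  W <- path4_weights()
  v <- c(u1 = 2, u2 = 2, u3 = 2, u4 = 2)
  expect_equal(local_moran(v, W)$I, rep(0, 4))
  expect_true(all(is.na(permutation_pvalues(v, W, 99, seed = 1))))
})

test_that("sum of local I equals n times global I on random fields", {
  blocks <- lattice_blocks(10, 10)
  W <- queen_weights(blocks)
  Wmat <- oracle_lattice_queen(10, 10)
  set.seed(55)
  for (rep in 1:5) {
    v <- stats::setNames(rnorm(100), W$ids)
    lm <- local_moran(v, W)
    g <- global_moran(v, W)
    expect_equal(sum(lm$I), 100 * g, tolerance = 1e-10)
    # and the global index agrees with explicit matrix algebra
    expect_equal(g, oracle_global_moran(as.numeric(v[W$ids]), Wmat),
                 tolerance = 1e-12)
  }
})

test_that("pseudo p-values are seeded, floored and island-aware", {
  W <- path4_weights()
  v <- c(u1 = 0, u2 = 0, u3 = 1, u4 = 4)
  p1 <- permutation_pvalues(v, W, n_permutations = 999, seed = 42)
  p2 <- permutation_pvalues(v, W, n_permutations = 999, seed = 42)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 1 / 1000))
  expect_error(permutation_pvalues(v, W, n_permutations = 50), ">= 99")
  # island unit: NA p, NS category
  geoms <- list(a = make_rect(0, 0, 1, 1), b = make_rect(1, 0, 2, 1),
                c = make_rect(0, 1, 1, 2), d = make_rect(9, 9, 10, 10))
  blocks <- block_set(data.frame(block_id = letters[1:4],
                                 adult_population = 1), geoms)
  Wq <- queen_weights(blocks)
  res <- lisa_cluster(c(a = 1, b = 2, c = 3, d = 99), Wq,
                      n_permutations = 99, seed = 1)
  expect_true(is.na(res$pseudo_p[res$id == "d"]))
  expect_identical(res$category[res$id == "d"], "NS")
})

test_that("categorization follows the quadrant rules", {
  lisa <- data.frame(id = letters[1:6],
                     z = c(1, -1, -1, 1, 0, 1),
                     lag = c(1, -1, 1, -1, 1, 0),
                     pseudo_p = c(1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 1e-4))
  expect_identical(unname(categorize(lisa, alpha = 0.01)),
                   c("HH", "LL", "LH", "HL", "NS", "NS"))
  lisa$pseudo_p <- 0.5
  expect_identical(unname(categorize(lisa, alpha = 0.01)), rep("NS", 6))
  # partition identity
  expect_identical(sum(table(categorize(lisa))), 6L)
})

test_that("value/weights id mismatch is an error", {
  W <- path4_weights()
  expect_error(local_moran(c(x1 = 1, x2 = 2, x3 = 3, x4 = 4), W),
               "do not match")
  expect_error(local_moran(c(1, 2, 3), W), "mismatch")
})

test_that("high-confidence categories are stable across seeds", {
  blocks <- lattice_blocks(8, 8)
  W <- queen_weights(blocks)
  set.seed(77)
  v <- rnorm(64)
  # plant a strong 2x2 high block
  hot <- which(blocks$df$row <= 2 & blocks$df$col <= 2)
  v[hot] <- v[hot] + 8
  v <- stats::setNames(v, W$ids)
  r1 <- lisa_cluster(v, W, n_permutations = 999, alpha = 0.01, seed = 1)
  r2 <- lisa_cluster(v, W, n_permutations = 999, alpha = 0.01, seed = 2)
  strong <- !is.na(r1$pseudo_p) & r1$pseudo_p <= 0.005
  expect_true(any(strong))
  expect_identical(r1$category[strong], r2$category[strong])
})
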