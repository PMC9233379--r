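# Local spatial analysis: queen-contiguity weights, local Moran's I,
# conditional permutation inference and the five-way LISA categorization.

#' Queen-contiguity spatial weights
#'
#' Two blocks are neighbors if their polygons share at least one boundary
#' point (an edge or a single corner).  Weights are row-standardized;
#' blocks with no neighbors are listed as islands.
#'
#' @param blocks a [block_set()].
#' @param snap contact tolerance in coordinate units (default 0: exact
#'   contact); useful for dirty real-world polygons.
#' @return A `spatial_weights` object: `ids`, `neighbors` (integer index
#'   lists), `weights` (per-neighbor weights), `islands` (character ids),
#'   `row_standardized = TRUE`.
#' @export
queen_weights <- function(blocks, snap = 0) {
  stopifnot(inherits(blocks, "block_set"), snap >= 0)
  ids <- blocks$df$block_id
  n <- length(ids)
  geoms <- blocks$geoms[ids]
  bxs <- t(vapply(geoms, bbox_of, numeric(4)))
  nbrs <- vector("list", n)
  for (i in seq_len(n)) nbrs[[i]] <- integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (bxs[i, 1L] > bxs[j, 3L] + snap || bxs[j, 1L] > bxs[i, 3L] + snap ||
          bxs[i, 2L] > bxs[j, 4L] + snap || bxs[j, 2L] > bxs[i, 4L] + snap)
        next
      if (rings_touch(geoms[[i]], geoms[[j]], snap = snap)) {
        nbrs[[i]] <- c(nbrs[[i]], j)
        nbrs[[j]] <- c(nbrs[[j]], i)
      }
    }
  }
  wts <- lapply(nbrs, function(nb)
    if (length(nb) > 0L) rep(1 / length(nb), length(nb)) else numeric(0))
  islands <- ids[lengths(nbrs) == 0L]
  structure(list(ids = ids, neighbors = nbrs, weights = wts,
                 islands = islands, row_standardized = TRUE),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("spatial_weights:", length(x$ids), "units, average",
      format(mean(lengths(x$neighbors)), digits = 3), "neighbors,",
      length(x$islands), "island(s)\n")
  invisible(x)
}

check_values_weights <- function(values, W) {
  stopifnot(inherits(W, "spatial_weights"))
  if (is.null(names(values))) {
    if (length(values) != length(W$ids))
      stop("values/weights length mismatch")
    names(values) <- W$ids
  }
  if (!setequal(names(values), W$ids))
    stop("values ids do not match weights ids")
  values[W$ids]
}

#' Local Moran's I
#'
#' For each unit `i`, `I_i = (z_i / m2) * sum_j w_ij z_j` with `z` the
#' deviations from the mean and `m2 = sum(z^2) / n` the sample variance.
#' Constant values yield `I_i = 0` everywhere by convention.
#'
#' @param values named (by unit id) or positionally matched numeric vector.
#' @param W a [queen_weights()] result.
#' @return Data frame `id`, `value`, `z`, `lag`, `I`, with `m2` and `n` as
#'   attributes.
#' @export
local_moran <- function(values, W) {
  values <- check_values_weights(values, W)
  n <- length(values)
  if (n - length(W$islands) < 3L)
    stop("need at least 3 non-island units")
  z <- values - mean(values)
  m2 <- sum(z ^ 2) / n
  lag <- vapply(seq_len(n), function(i) {
    nb <- W$neighbors[[i]]
    if (length(nb) == 0L) 0 else sum(W$weights[[i]] * z[nb])
  }, numeric(1))
  I <- if (m2 == 0) rep(0, n) else z / m2 * lag
  out <- data.frame(id = W$ids, value = as.numeric(values), z = as.numeric(z),
                    lag = lag, I = I, stringsAsFactors = FALSE)
  attr(out, "m2") <- m2
  attr(out, "n") <- n
  out
}

#' Conditional-permutation pseudo p-values for local Moran's I
#'
#' Per unit, the value is held fixed and the neighbors' deviations are
#' drawn without replacement from the remaining `n - 1` deviations;
#' `pseudo_p = (extreme count + 1) / (n_permutations + 1)`, one-sided in
#' the direction of the observed statistic.  Islands get `NA`.
#'
#' @inheritParams local_moran
#' @param n_permutations number of conditional permutations (>= 99;
#'   default 9999).
#' @param seed integer seed.
#' @return Numeric vector of pseudo p-values named by unit id.
#' @export
permutation_pvalues <- function(values, W, n_permutations = 9999L, seed = 1L) {
  values <- check_values_weights(values, W)
  if (n_permutations < 99L) stop("n_permutations must be >= 99")
  n <- length(values)
  z <- values - mean(values)
  m2 <- sum(z ^ 2) / n
  if (m2 == 0) {
    p <- rep(NA_real_, n); names(p) <- W$ids
    return(p)
  }
  p <- with_seed(seed,
                 cpp_perm_pvalues(as.numeric(z), m2, W$neighbors, W$weights,
                                  as.integer(n_permutations)))
  names(p) <- W$ids
  p
}

#' Five-way LISA categorization
#'
#' Significant units (`pseudo_p <= alpha`) are classified by the signs of
#' their deviation and spatial lag: `HH` (hot spot), `LL` (cold spot),
#' `LH` and `HL` (spatial outliers).  Everything else -- including islands
#' and units with a zero deviation or zero lag, whose quadrant is
#' undefined -- is `NS`.
#'
#' @param lisa data frame from [local_moran()] with a `pseudo_p` column.
#' @param alpha significance level (default 0.01).
#' @return Character vector of categories named by unit id.
#' @export
categorize <- function(lisa, alpha = 0.01) {
  stopifnot(all(c("z", "lag", "pseudo_p") %in% names(lisa)))
  cat <- rep("NS", nrow(lisa))
  sig <- !is.na(lisa$pseudo_p) & lisa$pseudo_p <= alpha &
    lisa$z != 0 & lisa$lag != 0
  cat[sig & lisa$z > 0 & lisa$lag > 0] <- "HH"
  cat[sig & lisa$z < 0 & lisa$lag < 0] <- "LL"
  cat[sig & lisa$z < 0 & lisa$lag > 0] <- "LH"
  cat[sig & lisa$z > 0 & lisa$lag < 0] <- "HL"
  names(cat) <- lisa$id
  cat
}

#' Full LISA analysis
#'
#' Convenience wrapper: [local_moran()], [permutation_pvalues()] and
#' [categorize()] in one call.
#'
#' @inheritParams permutation_pvalues
#' @param alpha significance level (default 0.01).
#' @return A `lisa_result` data frame `id`, `value`, `z`, `lag`, `I`,
#'   `pseudo_p`, `category`; attributes `m2`, `n`, `n_permutations`,
#'   `alpha`, `seed`, `islands`.
#' @export
lisa_cluster <- function(values, W, n_permutations = 9999L, alpha = 0.01,
                         seed = 1L) {
  lm <- local_moran(values, W)
  p <- permutation_pvalues(values, W, n_permutations = n_permutations,
                           seed = seed)
  lm$pseudo_p <- as.numeric(p)
  lm$category <- categorize(lm, alpha = alpha)
  structure(lm, class = c("lisa_result", "data.frame"),
            n_permutations = as.integer(n_permutations), alpha = alpha,
            seed = as.integer(seed), islands = W$islands)
}

#' @export
print.lisa_result <- function(x, ...) {
  cat("LISA (", attr(x, "n_permutations"), " permutations, alpha = ",
      attr(x, "alpha"), "):\n", sep = "")
  print(table(factor(x$category, levels = c("HH", "LL", "LH", "HL", "NS"))))
  invisible(x)
}

#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`; with row-standardized
#' weights and no islands, `sum_i I_i = n * I`.
#'
#' @inheritParams local_moran
#' @return Scalar global Moran's I.
#' @export
global_moran <- function(values, W) {
  values <- check_values_weights(values, W)
  z <- values - mean(values)
  s0 <- sum(unlist(W$weights))
  num <- sum(vapply(seq_along(z), function(i) {
    nb <- W$neighbors[[i]]
    if (length(nb) == 0L) 0 else z[i] * sum(W$weights[[i]] * z[nb])
  }, numeric(1)))
  (length(z) / s0) * num / sum(z ^ 2)
}
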