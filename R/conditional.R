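# Conditional LISA cluster tables: median splits, 2x2 cross-tabulations of
# hot/cold spots over covariate strata, the conditional-probability screen,
# and hot-vs-cold covariate profiles.

LISA_LEVELS <- c("HH", "LL", "LH", "HL", "NS")

#' Median split into low/high levels
#'
#' `low` iff the value is less than or equal to the median (ties go to
#' `low`, which keeps the rule deterministic and order-free).  A constant
#' vector degenerates to all-`low` with a warning.
#'
#' @param values numeric vector, non-empty.
#' @return Character vector of `"low"`/`"high"`, named like `values`.
#' @export
median_split <- function(values) {
  if (length(values) == 0L) stop("empty input")
  med <- stats::median(values)
  out <- ifelse(values <= med, "low", "high")
  if (all(out == "low")) warning("degenerate split: all values at or below the median")
  names(out) <- names(values)
  out
}

#' Conditional cluster table for a pair of stratifying variables
#'
#' Cross-tabulates LISA categories over the 2x2 strata of two low/high
#' variables, and reports, per variable and level, the fraction of hot
#' spots `P(level | HH)` and of cold spots `P(level | LL)` falling in that
#' level (the denominator is the number of HH, or LL, units).
#'
#' @param categories per-unit LISA categories (named by unit id).
#' @param levels_a,levels_b per-unit `"low"`/`"high"` levels, same units.
#' @param var_names length-2 character naming the pair.
#' @return A `conditional_table`: `pair`, `counts` (data frame with one row
#'   per stratum and one column per category), `hot_fractions` /
#'   `cold_fractions` (per variable, named low/high), `n_hot`, `n_cold`,
#'   `defined` (FALSE when there are no hot spots).
#' @export
conditional_cluster_table <- function(categories, levels_a, levels_b,
                                      var_names = c("A", "B")) {
  if (length(categories) != length(levels_a) ||
      length(categories) != length(levels_b))
    stop("length mismatch between categories and levels")
  if (!is.null(names(categories)) && !is.null(names(levels_a))) {
    if (!setequal(names(categories), names(levels_a)) ||
        !setequal(names(categories), names(levels_b)))
      stop("unit id mismatch between categories and levels")
    levels_a <- levels_a[names(categories)]
    levels_b <- levels_b[names(categories)]
  }
  la <- factor(levels_a, levels = c("low", "high"))
  lb <- factor(levels_b, levels = c("low", "high"))
  cat <- factor(categories, levels = LISA_LEVELS)
  tab <- table(la, lb, cat)
  counts <- as.data.frame.matrix(matrix(tab, nrow = 4L,
                                        dimnames = list(NULL, LISA_LEVELS)))
  counts <- cbind(expand.grid(level_a = c("low", "high"),
                              level_b = c("low", "high"),
                              stringsAsFactors = FALSE), counts)
  frac <- function(which_cat, lev) {
    tot <- sum(cat == which_cat)
    if (tot == 0L) return(c(low = NA_real_, high = NA_real_))
    c(low = sum(cat == which_cat & lev == "low") / tot,
      high = sum(cat == which_cat & lev == "high") / tot)
  }
  structure(list(pair = var_names,
                 counts = counts,
                 hot_fractions = list(frac("HH", la), frac("HH", lb)),
                 cold_fractions = list(frac("LL", la), frac("LL", lb)),
                 n_hot = sum(cat == "HH"), n_cold = sum(cat == "LL"),
                 defined = sum(cat == "HH") > 0L),
            class = "conditional_table")
}

#' @export
print.conditional_table <- function(x, ...) {
  cat("conditional_table:", x$pair[1L], "x", x$pair[2L],
      sprintf("(%d hot, %d cold)\n", x$n_hot, x$n_cold))
  print(x$counts)
  invisible(x)
}

#' Screen variable pairs by conditional hot-spot probability
#'
#' A pair is retained iff some level combination `(a, b)` has hot-spot
#' fraction strictly greater than `threshold` for both variables.
#'
#' @param tables list of [conditional_cluster_table()] results.
#' @param threshold screening threshold (default 0.6).
#' @return The retained sublist; each table gains a logical `retained`
#'   element, and the full decision vector is attached as attribute
#'   `retained_flags`.
#' @export
screen_pairs <- function(tables, threshold = 0.6) {
  flags <- vapply(tables, function(tb) {
    fa <- tb$hot_fractions[[1L]]; fb <- tb$hot_fractions[[2L]]
    if (anyNA(fa) || anyNA(fb)) return(FALSE)
    any(outer(fa > threshold, fb > threshold, `&`))
  }, logical(1))
  tables <- lapply(seq_along(tables), function(i) {
    tables[[i]]$retained <- flags[i]
    tables[[i]]
  })
  out <- tables[flags]
  attr(out, "retained_flags") <- flags
  out
}

#' Hot-vs-cold covariate profile
#'
#' Per covariate: the median over hot-spot (HH) blocks, over cold-spot
#' (LL) blocks, and over all analyzed blocks, plus the direction of the
#' hot-spot median relative to the overall median.
#'
#' @param categories per-unit LISA categories named by block id.
#' @param covariates data frame with `block_id` and numeric covariate
#'   columns.
#' @return Data frame `variable`, `median_hot`, `median_cold`,
#'   `median_all`, `direction` (+1, -1 or 0; `NA` medians give `NA`).
#' @export
spot_profile <- function(categories, covariates) {
  stopifnot("block_id" %in% names(covariates))
  rows <- match(names(categories), covariates$block_id)
  if (anyNA(rows)) stop("categories refer to unknown block ids")
  cov <- covariates[rows, , drop = FALSE]
  vars <- setdiff(names(cov), "block_id")
  vars <- vars[vapply(cov[vars], is.numeric, logical(1))]
  hot <- categories == "HH"; cold <- categories == "LL"
  med <- function(v, sel) if (any(sel)) stats::median(v[sel]) else NA_real_
  out <- do.call(rbind, lapply(vars, function(v) {
    mh <- med(cov[[v]], hot); mc <- med(cov[[v]], cold)
    ma <- stats::median(cov[[v]])
    data.frame(variable = v, median_hot = mh, median_cold = mc,
               median_all = ma,
               direction = if (is.na(mh)) NA_real_ else sign(mh - ma),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Hot-spot fractions by facility-access stratum
#'
#' Median-splits each facility-distance variable and reports the fraction
#' of hot spots (HH blocks) lying in the shorter-distance (`low`) stratum.
#' Blocks with undefined distances are excluded with a warning.
#'
#' @param categories per-unit LISA categories named by block id.
#' @param facility_distances data frame from
#'   [nearest_facility_distance()] (`block_id` + `dist_*` columns).
#' @return Data frame `type`, `n_hot`, `frac_shorter` (`NA` and flagged
#'   when there are no hot spots).
#' @export
facility_conditional <- function(categories, facility_distances) {
  stopifnot("block_id" %in% names(facility_distances))
  rows <- match(names(categories), facility_distances$block_id)
  if (anyNA(rows)) stop("categories refer to unknown block ids")
  fd <- facility_distances[rows, , drop = FALSE]
  dcols <- grep("^dist_", names(fd), value = TRUE)
  out <- do.call(rbind, lapply(dcols, function(cl) {
    d <- fd[[cl]]
    ok <- !is.na(d)
    if (!all(ok)) warning("excluding ", sum(!ok),
                          " block(s) with undefined distance for ", cl)
    lev <- median_split(d[ok])
    hot <- categories[ok] == "HH"
    n_hot <- sum(hot)
    data.frame(type = sub("^dist_", "", cl), n_hot = n_hot,
               frac_shorter = if (n_hot == 0L) NA_real_
                              else sum(hot & lev == "low") / n_hot,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
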