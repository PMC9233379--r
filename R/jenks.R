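# Exact Jenks natural-breaks classification (Fisher-style dynamic
# programming on the distinct sorted values, weighted by multiplicity).
# Running on distinct values guarantees that tied observations are never
# split across classes, so class membership is a function of the value
# alone and right-closed class intervals are well defined.

# weighted SSE of distinct values v[i..j] with counts w, via prefix sums
.jenks_prefix <- function(v, w) {
  list(W = cumsum(w), S = cumsum(w * v), Q = cumsum(w * v * v))
}

.sse <- function(pre, i, j) {
  W <- pre$W[j] - if (i > 1) pre$W[i - 1] else 0
  S <- pre$S[j] - if (i > 1) pre$S[i - 1] else 0
  Q <- pre$Q[j] - if (i > 1) pre$Q[i - 1] else 0
  max(0, Q - S * S / W)
}

#' Jenks natural-breaks classification
#'
#' Exact optimal partition of the values into `k` contiguous classes (on
#' the sorted scale) minimizing SDCM, the sum of squared deviations from
#' the class means, by dynamic programming.  Goodness of variance fit is
#' `GVF = 1 - SDCM/SDAM` with SDAM the squared deviations from the global
#' mean.  Classes are right-closed: a value equal to a break boundary
#' belongs to the lower class.
#'
#' @param values numeric vector (no NAs).
#' @param k number of classes, `1 <= k <=` number of distinct values.
#' @return A `jenks_breaks` object: `k`, `breaks` (length `k + 1`,
#'   strictly ascending, first/last are the data range), `labels`
#'   (per-value class index), `gvf`, `sdam`, `sdcm`.
#' @export
jenks_breaks <- function(values, k) {
  if (length(values) == 0L || anyNA(values)) stop("values must be non-empty, no NAs")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  sv <- sort(unique(values))
  m <- length(sv)
  if (k > m) stop("k exceeds the number of distinct values (", m, ")")
  w <- as.numeric(table(factor(values, levels = sv)))
  # center before forming prefix sums: Q - S^2/W cancels catastrophically
  # on raw values far from zero
  ctr <- sum(w * sv) / sum(w)
  pre <- .jenks_prefix(sv - ctr, w)
  # dp[c, j]: minimal SDCM of v[1..j] in c classes
  dp <- matrix(Inf, k, m)
  back <- matrix(0L, k, m)
  for (j in 1:m) { dp[1L, j] <- .sse(pre, 1L, j); back[1L, j] <- 1L }
  if (k > 1L) {
    for (cl in 2:k) {
      for (j in cl:m) {
        best <- Inf; bi <- cl
        for (i in cl:j) {
          cost <- dp[cl - 1L, i - 1L] + .sse(pre, i, j)
          if (cost < best) { best <- cost; bi <- i }
        }
        dp[cl, j] <- best; back[cl, j] <- bi
      }
    }
  }
  # backtrack class start indices
  starts <- integer(k)
  j <- m
  for (cl in k:1) { starts[cl] <- back[cl, j]; j <- starts[cl] - 1L }
  uppers <- c(starts[-1L] - 1L, m)
  breaks <- c(sv[1L], sv[uppers])
  lab_of_distinct <- rep(seq_len(k), times = uppers - starts + 1L)
  labels <- lab_of_distinct[match(values, sv)]
  # recompute the optimum stably from the chosen partition (the DP value
  # carries prefix-sum rounding error)
  sdcm <- sum(vapply(seq_len(k), function(cl) {
    sel <- lab_of_distinct == cl
    mu_c <- sum(w[sel] * sv[sel]) / sum(w[sel])
    sum(w[sel] * (sv[sel] - mu_c) ^ 2)
  }, numeric(1)))
  mu <- sum(w * sv) / sum(w)
  sdam <- sum(w * (sv - mu) ^ 2)
  gvf <- if (sdam == 0) 1 else 1 - sdcm / sdam
  structure(list(k = k, breaks = breaks, labels = labels,
                 gvf = gvf, sdam = sdam, sdcm = sdcm),
            class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat("jenks_breaks: k =", x$k, " GVF =", format(x$gvf, digits = 4), "\n")
  cat("  breaks:", paste(format(x$breaks, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of Jenks classes by goodness of variance fit
#'
#' Returns the smallest `k` in `k_range` whose GVF meets `gvf_target`; if
#' none does, the `k` maximizing GVF.  Candidates above the number of
#' distinct values are dropped.
#'
#' @param values numeric vector.
#' @param k_range candidate class counts (default 2--9).
#' @param gvf_target GVF threshold in `[0, 1]` (default 0.85).
#' @return Integer class count.
#' @export
select_k <- function(values, k_range = 2:9, gvf_target = 0.85) {
  if (length(k_range) == 0L) stop("k_range must be non-empty")
  k_range <- sort(unique(as.integer(k_range)))
  m <- length(unique(values))
  k_range <- k_range[k_range >= 1L & k_range <= m]
  if (length(k_range) == 0L) stop("no feasible k in k_range")
  gvfs <- vapply(k_range, function(k) jenks_breaks(values, k)$gvf, numeric(1))
  ok <- which(gvfs >= gvf_target)
  if (length(ok) > 0L) k_range[ok[1L]] else k_range[which.max(gvfs)]
}
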