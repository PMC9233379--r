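# Global clustering: Ripley's K with isotropic edge correction and a
# Monte-Carlo complete-spatial-randomness envelope.

# snap a ring that is an axis-aligned rectangle up to tiny projection noise
detect_rect <- function(ring, tol_rel = 1e-7) {
  ring <- as_ring(ring)
  if (nrow(ring) != 4L) return(NULL)
  xs <- sort(ring[, 1L]); ys <- sort(ring[, 2L])
  scale <- max(abs(ring), 1)
  tol <- tol_rel * scale
  if (abs(xs[1L] - xs[2L]) <= tol && abs(xs[3L] - xs[4L]) <= tol &&
      abs(ys[1L] - ys[2L]) <= tol && abs(ys[3L] - ys[4L]) <= tol) {
    c(x0 = mean(xs[1:2]), y0 = mean(ys[1:2]),
      x1 = mean(xs[3:4]), y1 = mean(ys[3:4]))
  } else NULL
}

#' Isotropic edge-correction weight
#'
#' Fraction of the circumference of the circle centered at `center` and
#' passing through `other` that lies inside the window: 1 when the circle
#' is entirely interior.  Closed form for rectangular windows, exact
#' circle/edge arc intersection otherwise.
#'
#' @param center,other length-2 planar points inside the window.
#' @param window window ring.
#' @return Weight in `(0, 1]`.
#' @export
edge_weight <- function(center, other, window) {
  window <- as_ring(window)
  r <- sqrt(sum((center - other) ^ 2))
  if (r == 0) stop("coincident points define no circle")
  rect <- detect_rect(window)
  if (!is.null(rect))
    cpp_edge_weight_rect(center[1L], center[2L], r,
                         rect["x0"], rect["y0"], rect["x1"], rect["y1"])
  else
    cpp_edge_weight_poly(center[1L], center[2L], r, window)
}

#' Default radius grid for a window
#'
#' 64 equally spaced radii from 0 (exclusive) to one quarter of the
#' shorter window extent, within which the rectangle edge-correction
#' closed form is exact.
#'
#' @param window window ring.
#' @param n number of radii.
#' @return Ascending numeric vector.
#' @export
default_radii <- function(window, n = 64L) {
  bb <- bbox_of(as_ring(window))
  tmax <- min(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"]) / 4
  seq(0, tmax, length.out = n + 1L)[-1L]
}

#' Edge-corrected Ripley's K function
#'
#' \code{K(t) = (A/N^2) sum_i sum_(j!=i) w(l_i,l_j)^(-1) 1(d_ij < t)}
#' over ordered pairs, with \code{w} the in-window circumference fraction
#' of the circle centered at \code{l_i} through \code{l_j}.  The indicator
#' is strict, so pairs at exactly distance \code{t} are excluded.
#'
#' @param pattern a [point_pattern()] with at least 2 points.
#' @param radii ascending positive radii; non-positive entries are dropped
#'   with a warning.  Defaults to [default_radii()].
#' @return Data frame `t`, `k`, `theo` (`pi t^2`).
#' @export
k_function <- function(pattern, radii = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 2L) stop("K function needs at least 2 points")
  if (is.null(radii)) radii <- default_radii(pattern$window)
  if (any(radii <= 0)) {
    warning("dropping non-positive radii")
    radii <- radii[radii > 0]
  }
  radii <- sort(radii)
  rect <- detect_rect(pattern$window)
  k <- if (!is.null(rect))
    cpp_k_rect(pattern$x, pattern$y, rect["x0"], rect["y0"],
               rect["x1"], rect["y1"], radii)
  else
    cpp_k_poly(pattern$x, pattern$y, pattern$window, pattern$area, radii)
  data.frame(t = radii, k = k, theo = pi * radii ^ 2)
}

#' Monte-Carlo CSR envelope and verdicts for Ripley's K
#'
#' Simulates `n_sims` patterns of `N` uniform points in the window; at each
#' radius the envelope bounds are the r-th smallest and r-th largest
#' simulated K with \code{r = ceiling(alpha * (n_sims + 1) / 2)} (pointwise, not
#' simultaneous).  Verdict per radius: `clustered` if the observed K lies
#' above the upper bound, `dispersed` below the lower bound, otherwise
#' `random`.
#'
#' @inheritParams k_function
#' @param n_sims number of CSR simulations (default 999); must satisfy
#'   `n_sims >= 1/alpha - 1`.
#' @param alpha significance level in (0, 1) (default 0.01).
#' @param seed integer seed.
#' @return A `k_result`: data frame `t`, `k`, `theo`, `lo`, `hi`,
#'   `verdict`, with `n_sims`, `alpha`, `r_order`, `seed` as attributes.
#' @export
csr_envelope <- function(pattern, radii = NULL, n_sims = 999L, alpha = 0.01,
                         seed = 1L) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (n_sims < 1 / alpha - 1)
    stop("n_sims must be at least 1/alpha - 1")
  if (is.null(radii)) radii <- default_radii(pattern$window)
  obs <- k_function(pattern, radii)
  radii <- obs$t
  rect <- detect_rect(pattern$window)
  sims <- with_seed(seed, {
    if (!is.null(rect))
      cpp_csr_k_rect(pattern$n, rect["x0"], rect["y0"], rect["x1"],
                     rect["y1"], radii, as.integer(n_sims))
    else
      cpp_csr_k_poly(pattern$n, pattern$window, pattern$area, radii,
                     as.integer(n_sims))
  })
  r <- ceiling(alpha * (n_sims + 1) / 2)
  srt <- apply(sims, 2L, sort)
  lo <- srt[r, ]
  hi <- srt[n_sims + 1L - r, ]
  verdict <- ifelse(obs$k > hi, "clustered",
                    ifelse(obs$k < lo, "dispersed", "random"))
  out <- data.frame(t = obs$t, k = obs$k, theo = obs$theo,
                    lo = lo, hi = hi, verdict = verdict,
                    stringsAsFactors = FALSE)
  structure(out, class = c("k_result", "data.frame"),
            n_sims = as.integer(n_sims), alpha = alpha,
            r_order = as.integer(r), seed = as.integer(seed))
}

#' @export
print.k_result <- function(x, ...) {
  v <- table(x$verdict)
  cat("Ripley K CSR envelope (", attr(x, "n_sims"), " sims, alpha = ",
      attr(x, "alpha"), "):\n", sep = "")
  for (nm in names(v)) cat("  ", nm, ": ", v[[nm]], " radii\n", sep = "")
  invisible(x)
}

#' Plot an observed K function against its CSR envelope
#'
#' @param x a `k_result` from [csr_envelope()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.k_result <- function(x, ...) {
  graphics::plot(x$t, x$k, type = "l", lwd = 2, xlab = "t", ylab = "K(t)", ...)
  graphics::lines(x$t, x$theo, col = "red", lty = 2)
  graphics::lines(x$t, x$lo, col = "grey50")
  graphics::lines(x$t, x$hi, col = "grey50")
  invisible(x)
}
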