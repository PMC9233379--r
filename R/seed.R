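#' Evaluate an expression under a temporary RNG seed
#'
#' All randomness in the package flows through this helper so that no
#' function disturbs the caller's global RNG state: the current
#' `.Random.seed` is saved, the requested seed installed, and the previous
#' state restored on exit.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a sub-seed in
#' `[1, 2^31 - 2]`, so that pipeline stages can be re-run individually and
#' still reproduce the full-run artifacts.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  out <- (abs(master) %% 2147483647) * 48271 %% 2147483647
  out <- (out + h) %% 2147483646 + 1
  as.integer(out)
}
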