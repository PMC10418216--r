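`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a root seed and a stream label
#'
#' Each stochastic operation draws from its own stream derived from the root
#' seed, so individual modules can be re-run reproducibly without replaying
#' the whole simulation.
#'
#' @param seed integer root seed.
#' @param key character stream label.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  v <- utf8ToInt(key)
  h <- sum(v * seq_along(v))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 131 + 17) %% 2147483629)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# data.frame constructor without the checking overhead of data.frame();
# all columns must be equal-length vectors
fast_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = c(NA_integer_, -length(x[[1]])))
}

#' Overlap length of half-open intervals
#'
#' Vectorised overlap in bp between `[a1, a2)` and `[b1, b2)` (all
#' coordinates 0-based half-open, the package-wide convention).
#'
#' @param a1,a2,b1,b2 interval bounds.
#' @return non-negative overlap lengths.
#' @export
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}
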