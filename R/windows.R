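#' Windowed methylation levels per context
#'
#' Summarises calls on a fixed genomic grid. Per window and context the level
#' is the count-weighted mean `sum(n_meth) / sum(n_total)` over cytosines of
#' that context in the window. A window-context with no covered cytosines
#' carries `NA`. `total_level` is the sum of the three context levels
#' (a missing context contributes 0 when at least one context is defined);
#' fully uncovered windows are not emitted.
#'
#' @param calls coverage-filtered calls data.frame.
#' @param width window width in bp (`>= 1`); 300 for DMR calling, 100000 for
#'   pooled mapping, 5000 for browser averaging.
#' @param grid_origin grid anchor (bp); windows start at
#'   `grid_origin + k * width`.
#' @return window-profile data.frame: chrom, start, end, level_CG, level_CHG,
#'   level_CHH, n_CG, n_CHG, n_CHH (covered cytosines), total_level.
#' @examples
#' calls <- data.frame(chrom = "c", pos = c(10, 20), strand = "+",
#'                     context = "CG", n_meth = c(2, 4), n_total = 4)
#' window_methylation(calls, width = 100)$level_CG  # 6/8
#' @export
window_methylation <- function(calls, width, grid_origin = 0L) {
  if (width <= 0) stop("width must be positive")
  if (!nrow(calls)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), level_CG = numeric(),
                      level_CHG = numeric(), level_CHH = numeric(),
                      n_CG = integer(), n_CHG = integer(), n_CHH = integer(),
                      total_level = numeric(), stringsAsFactors = FALSE))
  }
  win <- (calls$pos - grid_origin) %/% width
  ci <- factor(calls$chrom)
  wmin <- min(win)
  wkey <- (as.integer(ci) - 1) * (max(win) - wmin + 1) + (win - wmin)
  ctxi <- match(calls$context, CONTEXTS)
  uk <- sort(unique(wkey))
  uwin <- match(wkey, uk)
  g <- (uwin - 1L) * 3L + ctxi
  s <- rowsum(cbind(calls$n_meth, calls$n_total, 1L), g)
  gids <- as.integer(rownames(s))
  r <- (gids - 1L) %/% 3L + 1L
  cc <- (gids - 1L) %% 3L + 1L
  lev <- matrix(NA_real_, nrow = length(uk), ncol = 3,
                dimnames = list(NULL, CONTEXTS))
  cnt <- matrix(0L, nrow = length(uk), ncol = 3,
                dimnames = list(NULL, CONTEXTS))
  lev[cbind(r, cc)] <- s[, 1] / s[, 2]
  cnt[cbind(r, cc)] <- as.integer(s[, 3])
  pos_of <- match(uk, wkey)   # first call of each output window
  out <- fast_df(
    chrom = as.character(ci[pos_of]),
    start = as.integer(grid_origin + win[pos_of] * width),
    end = as.integer(grid_origin + (win[pos_of] + 1) * width),
    level_CG = unname(lev[, "CG"]), level_CHG = unname(lev[, "CHG"]),
    level_CHH = unname(lev[, "CHH"]),
    n_CG = unname(cnt[, "CG"]), n_CHG = unname(cnt[, "CHG"]),
    n_CHH = unname(cnt[, "CHH"]),
    total_level = unname(rowSums(lev, na.rm = TRUE)))
  attr(out, "width") <- as.integer(width)
  attr(out, "grid_origin") <- as.integer(grid_origin)
  out
}
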