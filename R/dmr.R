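check_same_grid <- function(a, b) {
  if (!identical(attr(a, "width"), attr(b, "width")) ||
      !identical(attr(a, "grid_origin"), attr(b, "grid_origin")))
    stop("window profiles are not on the same grid")
}

#' Call suppressor-hypermethylated DMRs by the retention/recovery rule
#'
#' Windows are classified on the fixed grid shared by the three profiles:
#' `retention_ratio` is the quadruple mutant's `total_level` relative to the
#' triple mutant's, and `recovery_ratio` is the suppressor's `total_level`
#' relative to the triple mutant's. A window passes when methylation retained
#' in the quadruple mutant is less than `retention_max` (strict) and
#' methylation recovered in the suppressor exceeds `recovery_min` (strict):
#' the regions that collapsed with the remodeler and came back in the
#' suppressor. Windows where the triple-mutant `total_level` is missing or
#' zero are skipped and reported via `attr(, "skipped")`.
#'
#' @param triple,quadruple,suppressor [window_methylation()] profiles on one
#'   grid (width 300 bp in the standard analysis).
#' @param retention_max,recovery_min rule thresholds (defaults 0.4 and 0.6).
#' @param recovery_mode `"vs_triple"` (default): recovery =
#'   suppressor/triple. `"rescaled"`: (suppressor − quadruple) /
#'   (triple − quadruple), recovery of the lost fraction.
#' @return DmrCall data.frame: chrom, start, end, retention_ratio,
#'   recovery_ratio, passed; `attr(, "skipped")` holds skipped windows.
#' @examples
#' # triple 0.8, quadruple 0.2, suppressor 0.6 -> retention 0.25,
#' # recovery 0.75 -> passed
#' @export
call_suppressor_dmrs <- function(triple, quadruple, suppressor,
                                 retention_max = 0.4, recovery_min = 0.6,
                                 recovery_mode = c("vs_triple", "rescaled")) {
  recovery_mode <- match.arg(recovery_mode)
  check_same_grid(triple, quadruple)
  check_same_grid(triple, suppressor)
  key <- function(p) paste(p$chrom, p$start, sep = "\r")
  kt <- key(triple)
  qa <- quadruple$total_level[match(kt, key(quadruple))]
  su <- suppressor$total_level[match(kt, key(suppressor))]
  tr <- triple$total_level
  usable <- !is.na(tr) & tr > 0 & !is.na(qa) & !is.na(su)
  retention <- qa / tr
  recovery <- if (recovery_mode == "vs_triple") su / tr
              else (su - qa) / (tr - qa)
  out <- data.frame(chrom = triple$chrom, start = triple$start,
                    end = triple$end,
                    retention_ratio = retention, recovery_ratio = recovery,
                    passed = usable & retention < retention_max &
                      recovery > recovery_min,
                    stringsAsFactors = FALSE)
  skipped <- out[!usable, c("chrom", "start", "end"), drop = FALSE]
  out <- out[usable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "width") <- attr(triple, "width")
  attr(out, "grid_origin") <- attr(triple, "grid_origin")
  attr(out, "skipped") <- skipped
  out
}

#' Intersect DMR calls across suppressor lines
#'
#' The shared set is the windows passing in every line; Venn counts give the
#' number of windows in each non-empty line-subset membership pattern; and
#' adjacent shared windows are merged into maximal runs (reconciling the
#' 300 bp calling grid with kb-scale merged DMRs).
#'
#' @param dmr_sets named list (>= 2) of [call_suppressor_dmrs()] results on
#'   a common grid.
#' @return list with `shared` (windows passed in all sets), `merged`
#'   (data.frame chrom, start, end, n_windows of maximal shared runs), and
#'   `venn` (named integer vector; names are `&`-joined set names).
#' @export
intersect_dmrs <- function(dmr_sets) {
  if (length(dmr_sets) < 2L) stop("need at least two DMR sets to intersect")
  if (is.null(names(dmr_sets)))
    names(dmr_sets) <- paste0("set", seq_along(dmr_sets))
  for (s in dmr_sets[-1]) check_same_grid(dmr_sets[[1]], s)
  width <- attr(dmr_sets[[1]], "width")
  passed_keys <- lapply(dmr_sets, function(d)
    paste(d$chrom[d$passed], d$start[d$passed], sep = "\r"))
  all_keys <- sort(unique(unlist(passed_keys)))
  member <- vapply(passed_keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  member <- matrix(member, nrow = length(all_keys),
                   dimnames = list(all_keys, names(dmr_sets)))
  pattern <- apply(member, 1, function(r)
    paste(names(dmr_sets)[r], collapse = "&"))
  venn <- table(pattern)
  venn <- stats::setNames(as.integer(venn), names(venn))
  shared_keys <- all_keys[rowSums(member) == length(dmr_sets)]
  parts <- if (length(shared_keys))
    do.call(rbind, strsplit(shared_keys, "\r", fixed = TRUE))
  else matrix(character(), ncol = 2)
  shared <- data.frame(chrom = parts[, 1],
                       start = as.integer(parts[, 2]),
                       stringsAsFactors = FALSE)
  shared$end <- shared$start + width
  shared <- shared[order(shared$chrom, shared$start), , drop = FALSE]
  merged <- merge_adjacent_windows(shared)
  list(shared = shared, merged = merged, venn = venn)
}

merge_adjacent_windows <- function(w) {
  if (!nrow(w))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  new_run <- c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] |
                 w$start[-1] != w$end[-nrow(w)])
  run <- cumsum(new_run)
  data.frame(chrom = tapply(w$chrom, run, `[`, 1),
             start = as.integer(tapply(w$start, run, min)),
             end = as.integer(tapply(w$end, run, max)),
             n_windows = as.integer(tapply(w$start, run, length)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Five-number summaries of window methylation inside a region
#'
#' Tukey five-number summary (min, lower hinge, median, upper hinge, max) of
#' `total_level` over the windows of each genotype's profile overlapping a
#' region — the numbers behind a per-genotype boxplot of a shared DMR.
#'
#' @param profiles named list of [window_methylation()] profiles.
#' @param region list or one-row data.frame with chrom, start, end.
#' @return data.frame: genotype, min, q1, median, q3, max, n_windows.
#' @export
boxplot_summary <- function(profiles, region) {
  stopifnot(length(profiles) >= 1, !is.null(names(profiles)))
  rows <- lapply(names(profiles), function(g) {
    p <- profiles[[g]]
    sel <- p$chrom == region$chrom &
      p$end > region$start & p$start < region$end
    v <- p$total_level[sel]
    v <- v[!is.na(v)]
    if (!length(v)) stop("region contains no windows for genotype ", g)
    f <- stats::fivenum(v)
    data.frame(genotype = g, min = f[1], q1 = f[2], median = f[3],
               q3 = f[4], max = f[5], n_windows = length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write merged DMRs as BED
#'
#' Score is the mean recovery ratio of the merged windows scaled by 1000 and
#' clamped to `[0, 1000]`.
#'
#' @param dmrs a [call_suppressor_dmrs()] result.
#' @param path output BED path.
#' @return `path` invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  p <- dmrs[dmrs$passed, , drop = FALSE]
  merged <- merge_adjacent_windows(p[c("chrom", "start", "end")])
  score <- vapply(seq_len(nrow(merged)), function(i) {
    sel <- p$chrom == merged$chrom[i] & p$start >= merged$start[i] &
      p$end <= merged$end[i]
    mean(p$recovery_ratio[sel])
  }, numeric(1))
  gr <- GenomicRanges::GRanges(
    seqnames = merged$chrom,
    ranges = IRanges::IRanges(start = merged$start + 1L, end = merged$end))
  gr$name <- sprintf("DMR_%d", seq_len(nrow(merged)))
  gr$score <- pmin(pmax(round(score * 1000), 0), 1000)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
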