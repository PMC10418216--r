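#' Pooled window profiles of phenotype groups
#'
#' Computes per-line window profiles and averages them within phenotype
#' groups with equal weight per line (unweighted mean of per-line levels;
#' windows a line does not cover are dropped from that line's contribution).
#'
#' @param line_calls named list of per-line calls data.frames.
#' @param phenotypes character vector (`"fertile"`/`"sterile"`), parallel to
#'   `line_calls` or named by line.
#' @param width window width (default 100 kb; use a width matched to the
#'   genome scale).
#' @return list with elements `fertile` and `sterile`, each a window-profile
#'   data.frame (chrom, start, end, level_CG/CHG/CHH as group means,
#'   total_level, n_lines).
#' @export
pool_profiles <- function(line_calls, phenotypes, width = 100000L) {
  stopifnot(length(line_calls) == length(phenotypes))
  if (!all(phenotypes %in% c("fertile", "sterile")))
    stop("phenotypes must be 'fertile' or 'sterile'")
  groups <- split(seq_along(line_calls), phenotypes)
  for (g in c("fertile", "sterile"))
    if (is.null(groups[[g]]) || !length(groups[[g]]))
      stop("empty phenotype group: ", g)
  pool_one <- function(idx) {
    profs <- lapply(line_calls[idx], window_methylation, width = width)
    long <- do.call(rbind, lapply(profs, function(p)
      p[c("chrom", "start", "end", "level_CG", "level_CHG", "level_CHH",
          "total_level")]))
    key <- paste(long$chrom, long$start, sep = "\r")
    agg <- function(v) tapply(v, key, mean, na.rm = TRUE)
    ks <- sort(unique(key))
    m <- cbind(level_CG = agg(long$level_CG)[ks],
               level_CHG = agg(long$level_CHG)[ks],
               level_CHH = agg(long$level_CHH)[ks],
               total_level = agg(long$total_level)[ks])
    n_lines <- tapply(rep(1L, length(key)), key, sum)[ks]
    parts <- do.call(rbind, strsplit(ks, "\r", fixed = TRUE))
    out <- data.frame(chrom = parts[, 1], start = as.integer(parts[, 2]),
                      stringsAsFactors = FALSE)
    out$end <- out$start + as.integer(width)
    out <- cbind(out, as.data.frame(m), n_lines = as.integer(n_lines))
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "width") <- as.integer(width)
    attr(out, "grid_origin") <- 0L
    out
  }
  list(fertile = pool_one(groups$fertile),
       sterile = pool_one(groups$sterile))
}

#' Scan for the region linked to the sterile phenotype
#'
#' Finds maximal runs of consecutive windows where the fertile pool exceeds
#' the sterile pool by at least `delta_min` in `total_level` (the causative
#' hypomethylated region is over-represented in the sterile pool, which is
#' therefore hypomethylated where linked). Runs are ranked by
#' `run length x mean delta`; the top run is the linked candidate.
#'
#' @param fertile,sterile pooled window profiles on a common grid.
#' @param delta_min minimum per-window `fertile - sterile` difference.
#' @param context `"total"` (default) or one of `CG`, `CHG`, `CHH` to scan a
#'   single context.
#' @return data.frame of candidate regions (chrom, start, end, n_windows,
#'   mean_delta, score), sorted by decreasing score; zero rows when no window
#'   exceeds `delta_min`.
#' @export
linked_region_scan <- function(fertile, sterile, delta_min = 0.2,
                               context = c("total", "CG", "CHG", "CHH")) {
  context <- match.arg(context)
  check_same_grid(fertile, sterile)
  col <- if (context == "total") "total_level" else paste0("level_", context)
  key <- function(p) paste(p$chrom, p$start, sep = "\r")
  m <- match(key(fertile), key(sterile))
  delta <- fertile[[col]] - sterile[[col]][m]
  ok <- !is.na(delta) & delta >= delta_min
  w <- fertile[ok, c("chrom", "start", "end"), drop = FALSE]
  if (!nrow(w))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      mean_delta = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  w$delta <- delta[ok]
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  width <- attr(fertile, "width")
  new_run <- c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] |
                 w$start[-1] != w$start[-nrow(w)] + width)
  run <- cumsum(new_run)
  out <- data.frame(
    chrom = tapply(w$chrom, run, `[`, 1),
    start = as.integer(tapply(w$start, run, min)),
    end = as.integer(tapply(w$end, run, max)),
    n_windows = as.integer(tapply(w$delta, run, length)),
    mean_delta = as.numeric(tapply(w$delta, run, mean)),
    row.names = NULL, stringsAsFactors = FALSE)
  out$score <- out$n_windows * out$mean_delta
  out[order(-out$score), , drop = FALSE]
}

#' Epigenotype marker positions from a line's methylation
#'
#' Models methylation-sensitive (McrBC-style) marker genotyping as a
#' thresholded local methylation call: the level in a window centred on the
#' marker classifies it as `ddm1_derived` (below `low`), `WT_derived` (above
#' `high`) or `ambiguous` (between, or uncovered).
#'
#' @param calls a line's calls data.frame.
#' @param markers data.frame with chrom, pos.
#' @param window centred window width in bp.
#' @param low,high classification thresholds on the evidence level.
#' @param context context used as evidence (default CG, the most bimodal
#'   between methylated and hypomethylated states in heterochromatin).
#' @return data.frame: chrom, pos, call, evidence (level or `NA`), covered.
#' @export
epigenotype_markers <- function(calls, markers, window = 2000L,
                                low = 0.2, high = 0.5, context = "CG") {
  stopifnot(low < high)
  cc <- calls[calls$context == context, , drop = FALSE]
  res <- lapply(split(seq_len(nrow(markers)), markers$chrom), function(mi) {
    ci <- cc[cc$chrom == markers$chrom[mi[1]], , drop = FALSE]
    o <- order(ci$pos)
    pos <- ci$pos[o]
    cm <- c(0, cumsum(ci$n_meth[o]))
    ct <- c(0, cumsum(ci$n_total[o]))
    lo <- findInterval(markers$pos[mi] - window / 2 - 0.5, pos)
    hi <- findInterval(markers$pos[mi] + window / 2 - 0.5, pos)
    tot <- ct[hi + 1L] - ct[lo + 1L]
    lev <- ifelse(tot > 0, (cm[hi + 1L] - cm[lo + 1L]) / tot, NA_real_)
    data.frame(chrom = markers$chrom[mi], pos = markers$pos[mi],
               call = ifelse(is.na(lev), "ambiguous",
                      ifelse(lev < low, "ddm1_derived",
                      ifelse(lev > high, "WT_derived", "ambiguous"))),
               evidence = lev, covered = tot > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(match(paste(out$chrom, out$pos),
                         paste(markers$chrom, markers$pos))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-line ddm1-derived spans from informative marker calls, as IRanges.
# Marker genotyping brackets each recombination breakpoint between adjacent
# discordant markers; two conventions resolve the uncertainty:
#  - "expansive": spans run out to the nearest discordant marker (or the
#    chromosome bounds), covering every position that could be ddm1-derived;
#  - "conservative": spans cover only the marker run itself, every position
#    that must be ddm1-derived.
line_ddm1_spans <- function(marker_calls, chrom_length,
                            mode = c("expansive", "conservative")) {
  mode <- match.arg(mode)
  mc <- marker_calls[marker_calls$call != "ambiguous", , drop = FALSE]
  mc <- mc[order(mc$pos), , drop = FALSE]
  if (!nrow(mc)) return(IRanges::IRanges())
  runs <- rle(mc$call)
  ends_i <- cumsum(runs$lengths)
  starts_i <- ends_i - runs$lengths + 1L
  spans <- lapply(which(runs$values == "ddm1_derived"), function(r) {
    i0 <- starts_i[r]; i1 <- ends_i[r]
    if (mode == "expansive") {
      left <- if (i0 == 1L) 0 else mc$pos[i0 - 1L]
      right <- if (i1 == nrow(mc)) chrom_length else mc$pos[i1 + 1L]
    } else {
      left <- mc$pos[i0]
      right <- mc$pos[i1] + 1L
    }
    IRanges::IRanges(start = left + 1L, end = right)  # 1-based closed
  })
  if (!length(spans)) return(IRanges::IRanges())
  do.call(c, spans)
}

#' Map the causative interval from marker calls and phenotypes
#'
#' Under a dominant causative epiallele, the locus must be `ddm1_derived` in
#' every sterile line and cannot lie where any fertile line is
#' `ddm1_derived`: the mapped interval is the intersection over sterile lines
#' of their ddm1-derived spans minus the union over fertile lines of theirs.
#' Because markers only bracket recombination breakpoints, sterile spans are
#' taken expansively (out to the nearest discordant marker) and fertile
#' spans conservatively (the marker run itself), so the true locus is never
#' excluded by breakpoint uncertainty. An empty intersection yields an
#' inconsistency report naming lines whose removal would restore a
#' non-empty interval.
#'
#' @param marker_calls named list (by line) of [epigenotype_markers()]
#'   results, all on one chromosome.
#' @param phenotypes named character vector by line
#'   (`"fertile"`/`"sterile"`).
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @return list with `interval` (data.frame chrom, start, end; 0-based
#'   half-open; possibly several disjoint pieces), `status`
#'   (`"consistent"`, `"unresolved"`, `"inconsistent"`) and
#'   `violating_lines`.
#' @export
map_interval <- function(marker_calls, phenotypes, chrom, chrom_length) {
  stopifnot(length(marker_calls) >= 1,
            all(names(marker_calls) %in% names(phenotypes)))
  ph <- phenotypes[names(marker_calls)]
  spans <- lapply(names(marker_calls), function(l)
    line_ddm1_spans(marker_calls[[l]], chrom_length,
                    mode = if (ph[[l]] == "sterile") "expansive"
                           else "conservative"))
  names(spans) <- names(marker_calls)
  sterile <- names(marker_calls)[ph == "sterile"]
  fertile <- names(marker_calls)[ph == "fertile"]
  whole <- IRanges::IRanges(start = 1L, end = chrom_length)
  as_df <- function(ir) {
    ir <- IRanges::reduce(ir)
    data.frame(chrom = rep(chrom, length(ir)),
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  }
  compute <- function(st, fe) {
    inter <- whole
    for (l in st) inter <- IRanges::intersect(inter, spans[[l]])
    for (l in fe) inter <- IRanges::setdiff(inter, spans[[l]])
    inter
  }
  # a panel is uninformative when no line carries an informative marker or
  # when no sterile line localizes the dominant epiallele: the interval then
  # defaults to the whole region, flagged unresolved
  any_informative <- any(vapply(marker_calls, function(mc)
    any(mc$call != "ambiguous"), logical(1)))
  if (!any_informative || !length(sterile))
    return(list(interval = as_df(compute(sterile, fertile)),
                status = "unresolved", violating_lines = character()))
  inter <- compute(sterile, fertile)
  if (length(inter) && sum(IRanges::width(inter)) > 0) {
    return(list(interval = as_df(inter), status = "consistent",
                violating_lines = character()))
  }
  # leave-one-out search for lines breaking consistency
  viol <- character()
  for (l in c(sterile, fertile)) {
    st <- setdiff(sterile, l); fe <- setdiff(fertile, l)
    if (length(st) || length(fe)) {
      alt <- compute(st, fe)
      if (length(alt) && sum(IRanges::width(alt)) > 0)
        viol <- c(viol, l)
    }
  }
  list(interval = as_df(IRanges::IRanges()), status = "inconsistent",
       violating_lines = viol)
}
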