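#' Define an element group for metaplotting
#'
#' @param name group label.
#' @param members data.frame with chrom, start, end, strand, name.
#' @param exclude character vector of member names to drop (e.g. the hairpin
#'   source element, which is excluded from its family's profile).
#' @return object of class `"element_group"`.
#' @export
element_group <- function(name, members, exclude = character()) {
  stopifnot(all(c("chrom", "start", "end", "strand", "name") %in%
                  names(members)))
  members <- members[!members$name %in% exclude, , drop = FALSE]
  if (!nrow(members)) stop("element group '", name, "' is empty")
  # overlap check within the group
  o <- order(members$chrom, members$start)
  ms <- members[o, ]
  same <- ms$chrom[-1] == ms$chrom[-nrow(ms)]
  if (nrow(ms) > 1 && any(same & ms$start[-1] < ms$end[-nrow(ms)]))
    stop("members of group '", name, "' overlap")
  structure(list(name = name, members = members, exclude = exclude),
            class = "element_group")
}

#' Element groups of a toy genome
#'
#' Convenience constructor of the two standard groups: the ATHILA5 family
#' excluding the hairpin source element, and all other ATHILA elements.
#'
#' @param genome a `toy_genome`.
#' @return named list of two [element_group()]s (`ATHILA5`, `ATHILA_other`).
#' @export
athila_groups <- function(genome) {
  ann <- genome$annotations
  list(
    ATHILA5 = element_group("ATHILA5",
                            ann[ann$role == "ATHILA5", , drop = FALSE],
                            exclude = "CEN5-ATHILA5"),
    ATHILA_other = element_group("ATHILA_other",
                                 ann[ann$role == "ATHILA_other", ,
                                     drop = FALSE]))
}

# per-chromosome (value*weight, weight) base arrays from a track or calls
signal_arrays <- function(x, chrom_lengths, context = NULL) {
  is_calls <- "n_total" %in% names(x)
  if (is_calls && !is.null(context))
    x <- x[x$context == context, , drop = FALSE]
  arr <- list()
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    V <- numeric(L); W <- numeric(L)
    xi <- x[x$chrom == chrom, , drop = FALSE]
    if (nrow(xi)) {
      if (is_calls) {
        idx <- xi$pos + 1L
        V[idx] <- V[idx] + xi$n_meth
        W[idx] <- W[idx] + xi$n_total
      } else {
        for (k in seq_len(nrow(xi))) {
          span <- (xi$start[k] + 1L):xi$end[k]
          V[span] <- V[span] + xi$value[k]
          W[span] <- W[span] + 1
        }
      }
    }
    arr[[chrom]] <- list(V = V, W = W)
  }
  arr
}

# weighted mean of the base signal over real-valued interval [a, b)
# (fractional overlap at the edges); NA when no weight
bin_mean <- function(V, W, a, b) {
  i0 <- floor(a); i1 <- ceiling(b)
  idx <- seq.int(max(i0, 0), min(i1, length(V)) - 1L)
  if (!length(idx)) return(NA_real_)
  ov <- pmin(idx + 1, b) - pmax(idx, a)
  ov[ov < 0] <- 0
  w <- W[idx + 1L] * ov
  if (sum(w) == 0) return(NA_real_)
  sum(V[idx + 1L] * ov) / sum(w)
}

#' Element-anchored average profile (metaplot)
#'
#' Rescales each element body to a fixed number of bins plus fixed-width
#' flanks, orients minus-strand elements 5'->3', and averages per-bin means
#' with equal weight per element (long elements do not dominate). For
#' methylation calls the profile is computed per cytosine context with
#' count-weighted per-bin means; for a track, values are averaged with
#' fractional base overlap (elements shorter than the bin count contribute
#' through interpolation and are flagged).
#'
#' @param x a calls data.frame (chrom, pos, context, n_meth, n_total) or a
#'   track data.frame (chrom, start, end, value).
#' @param group an [element_group()].
#' @param chrom_lengths named chromosome lengths (e.g.
#'   `nchar(genome$chromosomes)`).
#' @param body_bins,flank_bins,flank_bp binning layout: body bins, bins per
#'   flank, flank width in bp.
#' @param contexts contexts to profile for calls input (default all three).
#' @return object of class `"meta_profile"`: data.frame bin, section
#'   (`flank5`/`body`/`flank3`), signal (context name or `"signal"`), mean,
#'   n_elements; metadata (`group`, `body_bins`, `flank_bins`, `flank_bp`,
#'   `short_elements`) in attributes.
#' @export
metaprofile <- function(x, group, chrom_lengths,
                        body_bins = 40L, flank_bins = 10L, flank_bp = 500L,
                        contexts = CONTEXTS) {
  stopifnot(inherits(group, "element_group"))
  is_calls <- "n_total" %in% names(x)
  signals <- if (is_calls) contexts else "signal"
  members <- group$members
  short <- members$name[(members$end - members$start) < body_bins]

  bin_edges <- function(s, e) {
    f5 <- seq(s - flank_bp, s, length.out = flank_bins + 1L)
    bd <- seq(s, e, length.out = body_bins + 1L)
    f3 <- seq(e, e + flank_bp, length.out = flank_bins + 1L)
    list(a = c(f5[-length(f5)], bd[-length(bd)], f3[-length(f3)]),
         b = c(f5[-1], bd[-1], f3[-1]))
  }
  nb <- 2L * flank_bins + body_bins
  section <- rep(c("flank5", "body", "flank3"),
                 c(flank_bins, body_bins, flank_bins))

  out <- list()
  for (sg in signals) {
    arr <- signal_arrays(x, chrom_lengths,
                         context = if (is_calls) sg else NULL)
    per_el <- matrix(NA_real_, nrow = nrow(members), ncol = nb)
    for (k in seq_len(nrow(members))) {
      A <- arr[[members$chrom[k]]]
      ed <- bin_edges(members$start[k], members$end[k])
      v <- vapply(seq_len(nb), function(j)
        bin_mean(A$V, A$W, ed$a[j], ed$b[j]), numeric(1))
      if (members$strand[k] == "-") v <- rev(v)
      per_el[k, ] <- v
    }
    out[[sg]] <- data.frame(
      bin = seq_len(nb), section = section, signal = sg,
      mean = colMeans(per_el, na.rm = TRUE),
      n_elements = colSums(!is.na(per_el)),
      stringsAsFactors = FALSE)
  }
  prof <- do.call(rbind, out)
  prof$mean[is.nan(prof$mean)] <- NA_real_
  rownames(prof) <- NULL
  structure(prof, class = c("meta_profile", "data.frame"),
            group = group$name, body_bins = body_bins,
            flank_bins = flank_bins, flank_bp = flank_bp,
            short_elements = short)
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile of group", attr(x, "group"), "-",
      attr(x, "body_bins"), "body bins +", attr(x, "flank_bins"),
      "flank bins x", attr(x, "flank_bp"), "bp\n")
  for (sg in unique(x$signal)) {
    b <- x$mean[x$signal == sg & x$section == "body"]
    cat(sprintf("  %-6s body mean %.4f\n", sg, mean(b, na.rm = TRUE)))
  }
  invisible(x)
}

#' Mean body signal of a metaprofile
#'
#' @param profile a [metaprofile()] result.
#' @param signal signal/context name (default: the first present).
#' @return mean over body bins (NA-removed).
#' @export
body_mean <- function(profile, signal = NULL) {
  signal <- signal %||% profile$signal[1]
  mean(profile$mean[profile$signal == signal & profile$section == "body"],
       na.rm = TRUE)
}

#' ChIP enrichment track: log2(IP/input)
#'
#' With `normalize = "depth"` (default) both tracks are scaled to a common
#' total before the ratio, so the result is invariant under rescaling either
#' track by a positive scalar (sequencing-depth differences cancel; note
#' genuine genome-wide enrichment is also scaled out). With
#' `normalize = "none"` raw values are compared, so a uniform 4-fold IP
#' excess reads as 2.0 log2 units. Then `log2((ip + p) / (input + p))` is
#' computed bin-wise with pseudocount `p`.
#'
#' @param ip,input track data.frames on a common grid (chrom, start, end,
#'   value).
#' @param pseudocount pseudocount on (normalised) values.
#' @param normalize `"depth"` or `"none"`.
#' @return a track data.frame of log2 ratios.
#' @export
chip_enrichment <- function(ip, input, pseudocount = 0.5,
                            normalize = c("depth", "none")) {
  normalize <- match.arg(normalize)
  if (nrow(ip) != nrow(input) ||
      !all(ip$chrom == input$chrom & ip$start == input$start &
             ip$end == input$end))
    stop("ip and input tracks are not on a common grid")
  ti <- sum(ip$value); tn <- sum(input$value)
  if (ti <= 0 || tn <= 0) stop("zero-total track")
  if (normalize == "depth") {
    vi <- ip$value / ti * nrow(ip)
    vn <- input$value / tn * nrow(input)
  } else {
    vi <- ip$value
    vn <- input$value
  }
  data.frame(chrom = ip$chrom, start = ip$start, end = ip$end,
             value = log2((vi + pseudocount) / (vn + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Coarse per-context browser averages
#'
#' Count-weighted mean methylation per context on a fixed grid (default 5 kb
#' windows), in long format for track export; windows with no calls in a
#' context are absent.
#'
#' @param calls coverage-filtered calls data.frame.
#' @param width window width in bp.
#' @return data.frame chrom, start, end, context, level.
#' @export
window_average_track <- function(calls, width = 5000L) {
  prof <- window_methylation(calls, width = width)
  long <- do.call(rbind, lapply(CONTEXTS, function(ctx) {
    lv <- prof[[paste0("level_", ctx)]]
    ok <- which(!is.na(lv))
    data.frame(chrom = prof$chrom[ok], start = prof$start[ok],
               end = prof$end[ok], context = rep(ctx, length(ok)),
               level = lv[ok], stringsAsFactors = FALSE)
  }))
  long <- long[order(long$chrom, long$start, long$context), , drop = FALSE]
  rownames(long) <- NULL
  long
}
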