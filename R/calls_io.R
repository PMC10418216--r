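#' Retain calls with sufficient read support
#'
#' Keeps exactly the calls with `n_total >= min_reads`, preserving order.
#' The default reproduces standard long-read post-call filtering (calls at
#' positions with at least 3 reads retained).
#'
#' @param calls calls data.frame (chrom, pos, strand, context, n_meth,
#'   n_total).
#' @param min_reads minimum total reads, `>= 1`.
#' @return the filtered calls data.frame.
#' @export
filter_min_coverage <- function(calls, min_reads = 3L) {
  stopifnot(min_reads >= 1)
  out <- calls[calls$n_total >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert calls to a signed methylation track
#'
#' Scales each call's methylation ratio to `[0, 1]` and negates minus-strand
#' ratios, giving a single browser track where sign encodes strand: value is
#' `n_meth / n_total` on the plus strand and `-n_meth / n_total` on the minus
#' strand.
#'
#' @param calls coverage-filtered calls data.frame; `n_total` must be
#'   positive everywhere.
#' @return data.frame chrom, start, end (1 bp intervals, 0-based half-open),
#'   value in `[-1, 1]`.
#' @export
to_signed_track <- function(calls) {
  if (nrow(calls) && any(calls$n_total <= 0))
    stop("n_total must be positive; coverage-filter the calls first")
  ratio <- if (nrow(calls)) calls$n_meth / calls$n_total else numeric(0)
  data.frame(chrom = calls$chrom, start = calls$pos, end = calls$pos + 1L,
             value = ifelse(calls$strand == "-", -ratio, ratio),
             stringsAsFactors = FALSE)
}

#' Read and write per-cytosine call tables
#'
#' Two TSV dialects are supported:
#' * `"cx"` (Bismark-CX-like): chrom, 1-based position, strand, methylated
#'   count, unmethylated count, context. Converted to 0-based internally.
#' * `"bedmethyl"` (bedMethyl-like, 11 columns): chrom, 0-based start, end,
#'   context, score (coverage clamped to 1000), strand, start, end, RGB,
#'   coverage, percent methylated. On reading, the methylated count is
#'   recovered as `round(percent / 100 * coverage)`.
#'
#' Both round-trip all CytosineCall fields losslessly (percent is written at
#' full precision).
#'
#' @param calls calls data.frame.
#' @param path file path.
#' @param dialect `"cx"` or `"bedmethyl"` (must be named explicitly).
#' @return `write_calls()`: `path` invisibly. `read_calls()`: calls
#'   data.frame (chrom, pos, strand, context, n_meth, n_total).
#' @export
write_calls <- function(calls, path, dialect = c("cx", "bedmethyl")) {
  dialect <- match.arg(dialect)
  if (dialect == "cx") {
    df <- data.frame(calls$chrom, calls$pos + 1L, calls$strand, calls$n_meth,
                     calls$n_total - calls$n_meth, calls$context)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    pct <- ifelse(calls$n_total > 0, 100 * calls$n_meth / calls$n_total, 0)
    df <- data.frame(calls$chrom, calls$pos, calls$pos + 1L, calls$context,
                     pmin(calls$n_total, 1000L), calls$strand,
                     calls$pos, calls$pos + 1L, "0,0,0",
                     calls$n_total, format(pct, digits = 12, trim = TRUE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path, dialect = c("cx", "bedmethyl")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], "track"))
    lines <- lines[-1]
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      n_meth = integer(), n_total = integer(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (dialect == "cx") 6L else 11L
  nf <- lengths(fields)
  if (any(nf < need))
    stop("malformed line ", which(nf < need)[1], ": expected ", need,
         " tab-separated fields")
  m <- matrix(unlist(lapply(fields, `[`, seq_len(need))),
              ncol = need, byrow = TRUE)
  if (dialect == "cx") {
    n_meth <- as.integer(m[, 4]); n_un <- as.integer(m[, 5])
    bad <- which(is.na(n_meth) | is.na(n_un))
    if (length(bad)) stop("malformed line ", bad[1], ": non-integer counts")
    data.frame(chrom = m[, 1], pos = as.integer(m[, 2]) - 1L,
               strand = m[, 3], context = m[, 6],
               n_meth = n_meth, n_total = n_meth + n_un,
               stringsAsFactors = FALSE)
  } else {
    n_total <- as.integer(m[, 10]); pct <- as.numeric(m[, 11])
    bad <- which(is.na(n_total) | is.na(pct))
    if (length(bad)) stop("malformed line ", bad[1],
                          ": non-numeric coverage/percent")
    data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
               strand = m[, 6], context = m[, 4],
               n_meth = as.integer(round(pct / 100 * n_total)),
               n_total = n_total, stringsAsFactors = FALSE)
  }
}

#' Write / read a track as bedGraph
#'
#' @param track data.frame chrom, start (0-based), end, value.
#' @param path file path.
#' @return `path` invisibly, or the track data.frame.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score, stringsAsFactors = FALSE)
}
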