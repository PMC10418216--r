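#' Classify cytosine contexts on both strands of a DNA sequence
#'
#' Every C on the plus strand and every G (a C on the minus strand) is
#' assigned one of the three plant methylation contexts by the two bases
#' downstream read 5'->3' on the cytosine's own strand: `CG` (next base G),
#' `CHG` (next base H = A/C/T, then G), `CHH` (both downstream bases H).
#' Cytosines whose downstream dinucleotide contains N or runs off the
#' sequence end are `"undetermined"`.
#'
#' @param sequence a single DNA string over `{A,C,G,T,N}`.
#' @return data.frame with columns `pos` (0-based), `strand` (`"+"`/`"-"`),
#'   `context` (`CG`, `CHG`, `CHH`, `undetermined`), ordered by position then
#'   strand.
#' @examples
#' classify_contexts("ACGTA")  # C at pos 1 is CG (+); G at pos 2 is CG (-)
#' @export
classify_contexts <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("non-IUPAC character '", chars[bad[1]], "' at offset ", bad[1] - 1L)
  n <- length(chars)
  pad <- c(chars, "N", "N")          # run-off positions behave like N
  lead <- c("N", "N", chars)

  ctx_plus <- function(i) {
    d1 <- pad[i + 1L]; d2 <- pad[i + 2L]
    ifelse(d1 == "G", "CG",
    ifelse(d1 == "N" | d2 == "N", "undetermined",
    ifelse(d2 == "G", "CHG", "CHH")))
  }
  # minus strand: downstream bases of the C (= genomic G at i) are the
  # complements of positions i-1, i-2; complement is G iff genomic base is C
  ctx_minus <- function(i) {
    u1 <- lead[i + 1L]; u2 <- lead[i]   # genomic i-1, i-2 (1-based via pad)
    ifelse(u1 == "C", "CG",
    ifelse(u1 == "N" | u2 == "N", "undetermined",
    ifelse(u2 == "C", "CHG", "CHH")))
  }

  ip <- which(chars == "C")
  im <- which(chars == "G")
  out <- data.frame(
    pos = c(ip, im) - 1L,
    strand = rep(c("+", "-"), c(length(ip), length(im))),
    context = c(ctx_plus(ip), ctx_minus(im)),
    stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-cytosine template of a toy genome
#'
#' Classifies every cytosine of every chromosome and annotates it with the
#' simulation role governing its target methylation level (element >
#' satellite > gene > background precedence) and with membership in the
#' hairpin-homologous sub-span of ATHILA5 copies. Computing this once lets
#' many methylomes be simulated from the same genome cheaply.
#'
#' @param genome a `toy_genome`.
#' @return data.frame: chrom, pos, strand, context, role, hp_homolog;
#'   undetermined contexts are excluded.
#' @export
methylome_template <- function(genome) {
  stopifnot(inherits(genome, "toy_genome"))
  ann <- genome$annotations
  hp <- hairpin_of(genome)
  src <- hp$source; span <- hp$span
  rel <- c((span$start - src$start) / (src$end - src$start),
           (span$end - src$start) / (src$end - src$start))

  res <- lapply(names(genome$chromosomes), function(chrom) {
    ctx <- classify_contexts(genome$chromosomes[[chrom]])
    ctx <- ctx[ctx$context != "undetermined", , drop = FALSE]
    role <- rep("background", nrow(ctx))
    assign_role <- function(role, rows, label) {
      for (k in seq_len(nrow(rows))) {
        hit <- ctx$pos >= rows$start[k] & ctx$pos < rows$end[k]
        role[hit] <- label
      }
      role
    }
    a <- ann[ann$chrom == chrom, , drop = FALSE]
    role <- assign_role(role, a[a$role == "gene", ], "gene")
    role <- assign_role(role, a[a$role == "satellite_array", ],
                        "satellite_array")
    role <- assign_role(role, a[a$role == "ATHILA_other", ], "ATHILA_other")
    role <- assign_role(role, a[a$role == "ATHILA5", ], "ATHILA5")
    hp_hom <- rep(FALSE, nrow(ctx))
    a5 <- a[a$role == "ATHILA5", , drop = FALSE]
    for (k in seq_len(nrow(a5))) {
      w <- a5$end[k] - a5$start[k]
      s <- a5$start[k] + rel[1] * w
      e <- a5$start[k] + rel[2] * w
      hp_hom[ctx$pos >= s & ctx$pos < e] <- TRUE
    }
    cbind(data.frame(chrom = chrom, stringsAsFactors = FALSE), ctx,
          data.frame(role = role, hp_homolog = hp_hom,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "level_cache") <- new.env(parent = emptyenv())
  out
}
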