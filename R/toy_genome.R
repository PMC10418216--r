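#' Build a toy centromeric genome
#'
#' Generates a small multi-chromosome genome whose layout mirrors a plant
#' pericentromere: each chromosome carries a central satellite-repeat array
#' (180 bp tandem units) with retrotransposon elements embedded in it, genes
#' on the arms, and — on the focal chromosome — a family of `ATHILA5`-like
#' elements one of which (the last, named `CEN5-ATHILA5`) carries the span
#' later used to design an RNAi hairpin. Satellite arrays tile the centromere
#' interval except where elements are embedded. All coordinates are 0-based
#' half-open.
#'
#' @param config a [simulation_config()].
#' @param n_athila5 number of ATHILA5 copies on the focal chromosome (>= 2).
#' @param n_athila_other_focal ATHILA (non-ATHILA5) copies on the focal
#'   chromosome (>= 2); other chromosomes get `n_athila_other_per_chrom` each.
#' @param n_athila_other_per_chrom see above.
#' @param element_length,gene_length element and gene lengths in bp.
#' @param hairpin_fraction central fraction of the source element covered by
#'   the hairpin span.
#' @return an object of class `"toy_genome"`: list with `chromosomes` (named
#'   character vector of sequences), `annotations` (data.frame: chrom, start,
#'   end, strand, role, name), `centromeres` (data.frame: chrom, start, end),
#'   `focal_chrom`, and the generating `config`.
#' @examples
#' g <- build_toy_genome(simulation_config(seed = 1))
#' table(g$annotations$role)
#' @export
build_toy_genome <- function(config = simulation_config(),
                             n_athila5 = 3L,
                             n_athila_other_focal = 2L,
                             n_athila_other_per_chrom = 2L,
                             element_length = 2000L,
                             gene_length = 1500L,
                             hairpin_fraction = 0.7) {
  stopifnot(inherits(config, "epicen_config"))
  if (n_athila5 < 2L || n_athila_other_focal < 2L)
    stop("focal chromosome needs >= 2 ATHILA5 and >= 2 other ATHILA elements")
  lens <- config$chrom_lengths
  cen <- data.frame(chrom = names(lens),
                    start = as.integer(round(0.3 * lens)),
                    end = as.integer(round(0.7 * lens)),
                    stringsAsFactors = FALSE)
  if (any(element_length > cen$end - cen$start))
    stop("element longer than centromere interval")

  with_seed(derive_seed(config$seed, "toy_genome"), {
    unit <- paste(sample(c("A", "C", "G", "T"), 180, replace = TRUE),
                  collapse = "")
    ann <- list()
    seqs <- character(length(lens))
    names(seqs) <- names(lens)
    for (ci in seq_along(lens)) {
      chrom <- names(lens)[ci]
      L <- lens[[ci]]
      cs <- cen$start[ci]; ce <- cen$end[ci]
      base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      # tile the centromere with the satellite unit
      tile <- strsplit(strrep(unit, ceiling((ce - cs) / 180)), "")[[1]]
      base[(cs + 1):ce] <- tile[seq_len(ce - cs)]

      is_focal <- chrom == config$focal_chrom
      n_el <- if (is_focal) n_athila5 + n_athila_other_focal
              else n_athila_other_per_chrom
      gap <- ((ce - cs) - n_el * element_length) / (n_el + 1)
      if (gap < 0) stop("element longer than centromere interval")
      starts <- as.integer(round(cs + gap * seq_len(n_el) +
                                   element_length * (seq_len(n_el) - 1)))
      roles <- if (is_focal) {
        # interleave so ATHILA5 copies are interspersed among other ATHILA
        r <- rep("ATHILA_other", n_el)
        r[as.integer(round(seq(1, n_el, length.out = n_athila5)))] <- "ATHILA5"
        r
      } else rep("ATHILA_other", n_el)
      el_names <- paste0(chrom, "_", roles, "_", stats::ave(seq_len(n_el),
                         roles, FUN = seq_along))
      for (k in seq_len(n_el)) {
        s <- starts[k]; e <- s + element_length
        base[(s + 1):e] <- sample(c("A", "C", "G", "T"), element_length,
                                  replace = TRUE)
        ann[[length(ann) + 1]] <- data.frame(
          chrom = chrom, start = s, end = e,
          strand = if (k %% 2L == 1L) "+" else "-",
          role = roles[k], name = el_names[k], stringsAsFactors = FALSE)
      }
      # genes: two per arm
      gene_starts <- as.integer(round(c(0.05, 0.18) * L))
      gene_starts <- c(gene_starts, as.integer(round(c(0.78, 0.9) * L)))
      for (k in seq_along(gene_starts)) {
        s <- gene_starts[k]; e <- s + gene_length
        ann[[length(ann) + 1]] <- data.frame(
          chrom = chrom, start = s, end = e,
          strand = if (k %% 2L == 1L) "+" else "-",
          role = "gene", name = paste0(chrom, "_gene_", k),
          stringsAsFactors = FALSE)
      }
      ann[[length(ann) + 1]] <- data.frame(
        chrom = chrom, start = cs, end = ce, strand = "*",
        role = "satellite_array", name = paste0(chrom, "_cen_satellite"),
        stringsAsFactors = FALSE)
      seqs[chrom] <- paste(base, collapse = "")
    }
    ann <- do.call(rbind, ann)

    # hairpin span: central fraction of the last ATHILA5 copy on the focal
    # chromosome; that copy is the hairpin source ("CEN5-ATHILA5")
    a5 <- ann[ann$role == "ATHILA5" & ann$chrom == config$focal_chrom, ]
    src <- a5[nrow(a5), ]
    ann$name[ann$name == src$name] <- "CEN5-ATHILA5"
    pad <- (1 - hairpin_fraction) / 2
    hp <- data.frame(
      chrom = src$chrom,
      start = as.integer(round(src$start + pad * (src$end - src$start))),
      end = as.integer(round(src$end - pad * (src$end - src$start))),
      strand = src$strand, role = "hairpin_span", name = "hp5",
      stringsAsFactors = FALSE)
    ann <- rbind(ann, hp)
    rownames(ann) <- NULL

    structure(list(chromosomes = seqs,
                   annotations = ann,
                   centromeres = cen,
                   focal_chrom = config$focal_chrom,
                   config = config),
              class = "toy_genome")
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", length(x$chromosomes), "chromosomes,",
      sum(nchar(x$chromosomes)), "bp total\n")
  cat("  focal chromosome:", x$focal_chrom, "\n")
  print(table(x$annotations$role))
  invisible(x)
}

#' Hairpin source element and span of a toy genome
#'
#' @param genome a [build_toy_genome()] result.
#' @return list with `source` (annotation row of the source element) and
#'   `span` (annotation row of the hairpin span).
#' @export
hairpin_of <- function(genome) {
  ann <- genome$annotations
  list(source = ann[ann$name == "CEN5-ATHILA5", , drop = FALSE],
       span = ann[ann$role == "hairpin_span", , drop = FALSE])
}

#' Write a toy genome to FASTA
#'
#' @param genome a `toy_genome`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Write toy-genome annotations to BED6 or GFF3
#'
#' BED is emitted 0-based half-open; GFF3 1-based closed (conversion at the
#' boundary, coordinates are 0-based half-open internally).
#'
#' @param genome a `toy_genome`.
#' @param path output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(genome, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  ann <- genome$annotations
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ifelse(ann$strand == "*", "*", ann$strand))
  gr$name <- ann$name
  if (format == "bed") {
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "BED")
  } else {
    gr$type <- ann$role
    gr$ID <- ann$name
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}
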