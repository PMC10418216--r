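#' Simulate epigenetic recombinant lines
#'
#' Models the construction of recombinant lines in which hypomethylated
#' chromosomal regions inherited from a remodeler mutant segregate in a
#' methylated background: each line receives, for every chromosome, one
#' recombinant gamete from an F1 that carries one hypomethylated
#' (`ddm1_derived`) and one methylated (`WT_derived`) homolog. Crossover
#' counts per region are Poisson at `crossover_rate_arm` (each arm) and
#' `crossover_rate_centromere` (centromere interval), placed uniformly within
#' the region; the starting haplotype is equiprobable. The phenotype is
#' sterile iff the causative interval is entirely `ddm1_derived` (the
#' epiallele acts dominantly over the methylated homolog contributed by the
#' recurrent parent).
#'
#' @param genome a `toy_genome`.
#' @param config a [simulation_config()]; `n_recombinant_lines` lines drawn.
#' @param causative data.frame (chrom, start, end) of the causative interval;
#'   defaults to the hairpin source element on the focal chromosome.
#' @param seed optional seed override.
#' @return list of `epigenotype_mosaic` objects: each has `line_id`, `blocks`
#'   (data.frame chrom, start, end, origin in {ddm1_derived, WT_derived};
#'   blocks partition each chromosome) and `phenotype` in {fertile, sterile}.
#' @export
simulate_recombinant_lines <- function(genome, config, causative = NULL,
                                       seed = NULL) {
  stopifnot(inherits(genome, "toy_genome"))
  n <- config$n_recombinant_lines
  if (n < 1L) stop("at least one recombinant line must be requested")
  causative <- causative %||% {
    src <- hairpin_of(genome)$source
    data.frame(chrom = src$chrom, start = src$start, end = src$end)
  }
  lens <- config$chrom_lengths
  cen <- genome$centromeres
  seed <- seed %||% derive_seed(config$seed, "recombinant_lines")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      blocks <- lapply(names(lens), function(chrom) {
        L <- lens[[chrom]]
        cs <- cen$start[cen$chrom == chrom]
        ce <- cen$end[cen$chrom == chrom]
        regions <- rbind(c(0, cs, config$crossover_rate_arm),
                         c(cs, ce, config$crossover_rate_centromere),
                         c(ce, L, config$crossover_rate_arm))
        xo <- unlist(lapply(seq_len(nrow(regions)), function(r) {
          k <- stats::rpois(1, regions[r, 3])
          if (k == 0) numeric(0)
          else stats::runif(k, regions[r, 1], regions[r, 2])
        }))
        bp <- sort(unique(floor(xo)))
        edges <- c(0, bp, L)
        origin0 <- sample(c("ddm1_derived", "WT_derived"), 1L)
        origins <- rep(c(origin0,
                         setdiff(c("ddm1_derived", "WT_derived"), origin0)),
                       length.out = length(edges) - 1L)
        data.frame(chrom = chrom,
                   start = as.integer(edges[-length(edges)]),
                   end = as.integer(edges[-1]),
                   origin = origins, stringsAsFactors = FALSE)
      })
      blocks <- do.call(rbind, blocks)
      phen <- if (interval_origin(blocks, causative) == "ddm1_derived")
        "sterile" else "fertile"
      structure(list(line_id = sprintf("line_%02d", i),
                     blocks = blocks, phenotype = phen),
                class = "epigenotype_mosaic")
    })
  })
}

# origin of an interval in a block mosaic: "ddm1_derived" only when the whole
# interval is ddm1-derived, else "WT_derived"
interval_origin <- function(blocks, interval) {
  b <- blocks[blocks$chrom == interval$chrom[1], , drop = FALSE]
  ov <- interval_overlap(b$start, b$end, interval$start[1], interval$end[1])
  ddm1 <- sum(ov[b$origin == "ddm1_derived"])
  if (ddm1 == interval$end[1] - interval$start[1]) "ddm1_derived"
  else "WT_derived"
}

#' @export
print.epigenotype_mosaic <- function(x, ...) {
  cat("epigenotype_mosaic", x$line_id, "-", x$phenotype, "\n")
  cat("  ", nrow(x$blocks), "blocks;",
      sum(x$blocks$end - x$blocks$start)[1], "bp\n")
  invisible(x)
}

#' Simulate the methylome of one recombinant line
#'
#' Composes per-block methylation: positions in `ddm1_derived` blocks draw
#' from the hypomethylated genotype's target levels, positions in
#' `WT_derived` blocks from the methylated genotype's.
#'
#' @param genome a `toy_genome`.
#' @param mosaic an `epigenotype_mosaic`.
#' @param config a [simulation_config()].
#' @param template optional precomputed [methylome_template()].
#' @param wt,ddm1 genotype specs for the two block origins (defaults:
#'   `genotype_preset("wildtype")`, `genotype_preset("hypomethylated")`).
#' @param seed optional seed override (default derives from the line id).
#' @return a calls data.frame as in [simulate_methylome()].
#' @export
simulate_line_methylome <- function(genome, mosaic, config, template = NULL,
                                    wt = genotype_preset("wildtype"),
                                    ddm1 = genotype_preset("hypomethylated"),
                                    seed = NULL) {
  stopifnot(inherits(mosaic, "epigenotype_mosaic"))
  template <- template %||% methylome_template(genome)
  lv_wt <- target_levels_for(template, wt)
  lv_dd <- target_levels_for(template, ddm1)
  b <- mosaic$blocks
  is_ddm1 <- logical(nrow(template))
  for (chrom in unique(b$chrom)) {
    bc <- b[b$chrom == chrom, , drop = FALSE]
    sel <- template$chrom == chrom
    idx <- findInterval(template$pos[sel], bc$start)
    is_ddm1[sel] <- bc$origin[idx] == "ddm1_derived"
  }
  level <- ifelse(is_ddm1, lv_dd, lv_wt)
  seed <- seed %||% derive_seed(config$seed,
                                paste0("line_methylome:", mosaic$line_id))
  with_seed(seed, {
    n_total <- stats::rpois(nrow(template), config$coverage_mean)
    keep <- n_total > 0L
    fast_df(chrom = template$chrom[keep], pos = template$pos[keep],
            strand = template$strand[keep],
            context = template$context[keep],
            n_meth = stats::rbinom(sum(keep), n_total[keep], level[keep]),
            n_total = n_total[keep])
  })
}
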