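#' Simulate a multi-suppressor methylome panel with a planted shared locus
#'
#' Builds the input set of the shared-DMR analysis: a methylated
#' triple-mutant methylome, a hypomethylated quadruple-mutant methylome, and
#' `n_suppressors` suppressor methylomes that share one common
#' hypermethylated locus (planted in the focal-chromosome centromere) and
#' each carry `n_private` private hypermethylated loci in the centromeres of
#' the other chromosomes. Hypermethylation is in all three contexts.
#'
#' @param genome a `toy_genome`.
#' @param config a [simulation_config()].
#' @param n_suppressors number of suppressor lines (>= 2).
#' @param n_private private hypermethylated loci per suppressor.
#' @param locus_length hyper-locus length in bp.
#' @param template optional precomputed [methylome_template()].
#' @return list: `triple`, `quadruple` (calls data.frames), `suppressors`
#'   (named list of calls data.frames), `common_locus` (data.frame chrom,
#'   start, end), `private_loci` (named list of data.frames).
#' @export
simulate_suppressor_panel <- function(genome, config, n_suppressors = 4L,
                                      n_private = 5L, locus_length = 1200L,
                                      template = NULL) {
  stopifnot(n_suppressors >= 2L)
  template <- template %||% methylome_template(genome)
  cen <- genome$centromeres
  fc <- cen[cen$chrom == genome$focal_chrom, ]
  common <- data.frame(chrom = fc$chrom,
                       start = fc$start + 2000L,
                       end = fc$start + 2000L + locus_length,
                       stringsAsFactors = FALSE)
  chroms <- cen$chrom
  private <- lapply(seq_len(n_suppressors), function(k) {
    rows <- lapply(seq_len(n_private), function(j) {
      ci <- ((k + j) %% length(chroms)) + 1L
      span <- cen$end[ci] - cen$start[ci]
      off <- 5000L + ((j * 1700L + k * 330L) %% (span - 5000L - 900L))
      data.frame(chrom = chroms[ci], start = cen$start[ci] + off,
                 end = cen$start[ci] + off + 900L, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(private) <- paste0("suppressor_", seq_len(n_suppressors))

  triple <- simulate_methylome(genome, genotype_preset("wildtype",
                                                       name = "triple"),
                               config, template)
  quadruple <- simulate_methylome(genome,
                                  genotype_preset("hypomethylated",
                                                  name = "quadruple"),
                                  config, template)
  sups <- lapply(seq_len(n_suppressors), function(k) {
    spec <- genotype_preset("suppressor",
                            name = paste0("suppressor_", k),
                            hyper_loci = rbind(common, private[[k]]))
    simulate_methylome(genome, spec, config, template)
  })
  names(sups) <- names(private)
  list(triple = triple, quadruple = quadruple, suppressors = sups,
       common_locus = common, private_loci = private)
}

#' Call and intersect suppressor DMRs on a simulated panel
#'
#' Convenience wrapper: coverage-filters the panel's calls, windows them on
#' the `width` grid, applies the retention/recovery rule per suppressor and
#' intersects across suppressors.
#'
#' @param panel a [simulate_suppressor_panel()] result.
#' @param width DMR window width (default 300 bp).
#' @param min_reads coverage filter threshold.
#' @param ... passed to [call_suppressor_dmrs()].
#' @return an [intersect_dmrs()] result.
#' @export
panel_shared_dmrs <- function(panel, width = 300L, min_reads = 3L, ...) {
  wprof <- function(calls)
    window_methylation(filter_min_coverage(calls, min_reads), width = width)
  tw <- wprof(panel$triple)
  qw <- wprof(panel$quadruple)
  sets <- lapply(panel$suppressors, function(s)
    call_suppressor_dmrs(tw, qw, wprof(s), ...))
  intersect_dmrs(sets)
}
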