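#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data module: genome scale, WGBS-like
#' coverage, recombinant-panel design, and cytology scoring sizes. Defaults
#' reproduce the study conditions the analyses assume: a five-chromosome toy
#' genome (so per-chromosome attribution remains meaningful), 100 scored
#' anaphase cells per genotype, 30 chromocenters, and suppressor segregant
#' pools of 15 suppressors versus 45 non-suppressors.
#'
#' @param seed integer root seed; every stochastic operation derives its own
#'   stream from it (see [derive_seed()]).
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param focal_chrom chromosome carrying the causative centromeric epiallele.
#' @param coverage_mean mean reads per cytosine (Poisson) for simulated calls.
#' @param n_recombinant_lines number of epigenetic recombinant lines per panel.
#' @param crossover_rate_arm,crossover_rate_centromere expected crossovers per
#'   chromosome region per meiosis; the centromeric rate must be the smaller,
#'   reflecting crossover suppression in centromeric regions.
#' @param n_cells_scored anaphase cells scored per genotype.
#' @param n_chromocenters chromocenter measurements per genotype.
#' @param suppressor_pool_sizes named vector `c(suppressor=, nonsuppressor=)`,
#'   plants per segregant pool.
#' @param chip_binwidth,chip_depth bin width (bp) and mean per-bin depth of
#'   simulated ChIP/input tracks.
#' @return an object of class `"epicen_config"` (a validated list).
#' @examples
#' cfg <- simulation_config(seed = 1)
#' cfg$suppressor_pool_sizes
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = stats::setNames(rep(50000L, 5),
                                                              paste0("Chr", 1:5)),
                              focal_chrom = "Chr5",
                              coverage_mean = 20,
                              n_recombinant_lines = 20L,
                              crossover_rate_arm = 1,
                              crossover_rate_centromere = 0.05,
                              n_cells_scored = 100L,
                              n_chromocenters = 30L,
                              suppressor_pool_sizes = c(suppressor = 15L,
                                                        nonsuppressor = 45L),
                              chip_binwidth = 50L,
                              chip_depth = 20) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must be uniquely named")
  if (any(chrom_lengths < 10000))
    stop("chromosome lengths must be >= 10 kb")
  if (!focal_chrom %in% names(chrom_lengths))
    stop("focal_chrom not among chrom_lengths names")
  if (!(crossover_rate_centromere < crossover_rate_arm))
    stop("crossover_rate_centromere must be < crossover_rate_arm")
  counts <- c(coverage_mean, n_recombinant_lines, n_cells_scored,
              n_chromocenters, suppressor_pool_sizes, chip_binwidth, chip_depth)
  if (any(counts <= 0)) stop("all counts and rates must be positive")
  structure(list(
    seed = as.integer(seed),
    chrom_lengths = chrom_lengths,
    focal_chrom = focal_chrom,
    coverage_mean = coverage_mean,
    n_recombinant_lines = as.integer(n_recombinant_lines),
    crossover_rate_arm = crossover_rate_arm,
    crossover_rate_centromere = crossover_rate_centromere,
    n_cells_scored = as.integer(n_cells_scored),
    n_chromocenters = as.integer(n_chromocenters),
    suppressor_pool_sizes = suppressor_pool_sizes,
    chip_binwidth = as.integer(chip_binwidth),
    chip_depth = chip_depth
  ), class = "epicen_config")
}

#' @export
print.epicen_config <- function(x, ...) {
  cat("epicen simulation config\n")
  cat("  seed:", x$seed, "\n")
  cat("  genome:", length(x$chrom_lengths), "chromosomes,",
      sum(as.numeric(x$chrom_lengths)), "bp; focal:", x$focal_chrom, "\n")
  cat("  coverage_mean:", x$coverage_mean,
      " lines:", x$n_recombinant_lines, "\n")
  cat("  crossover rates (arm/cen):", x$crossover_rate_arm, "/",
      x$crossover_rate_centromere, "\n")
  cat("  cells scored:", x$n_cells_scored,
      " chromocenters:", x$n_chromocenters, "\n")
  cat("  pools:", x$suppressor_pool_sizes["suppressor"], "suppressors /",
      x$suppressor_pool_sizes["nonsuppressor"], "non-suppressors\n")
  invisible(x)
}
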