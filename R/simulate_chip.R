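#' Default ChIP enrichment multipliers per genotype state
#'
#' Heterochromatin-mark (H3K9me2-like) enrichment over input per annotation
#' role: strong at ATHILA elements in the methylated state, collapsed in the
#' hypomethylated state, restored specifically at ATHILA5 under the hairpin.
#'
#' @param which `"wildtype"`, `"hypomethylated"` or `"hairpin_rescued"`.
#' @return named numeric vector of multipliers over `SIM_ROLES`.
#' @export
chip_multipliers <- function(which = c("wildtype", "hypomethylated",
                                       "hairpin_rescued")) {
  which <- match.arg(which)
  switch(which,
    wildtype = c(satellite_array = 2, ATHILA5 = 4, ATHILA_other = 4,
                 gene = 1, background = 1),
    hypomethylated = c(satellite_array = 1.2, ATHILA5 = 1.2,
                       ATHILA_other = 1.2, gene = 1, background = 1),
    hairpin_rescued = c(satellite_array = 1.2, ATHILA5 = 3.5,
                        ATHILA_other = 1.2, gene = 1, background = 1))
}

#' Simulate a ChIP/input coverage track pair
#'
#' Bins the genome at `config$chip_binwidth` and draws input counts Poisson
#' around `config$chip_depth`; IP counts are Poisson around input expectation
#' times the role multiplier at the bin midpoint. Both tracks cover the
#' genome without gaps.
#'
#' @param genome a `toy_genome`.
#' @param multipliers named non-negative numeric vector over roles (see
#'   [chip_multipliers()]).
#' @param config a [simulation_config()].
#' @param seed optional seed override.
#' @return list of two track data.frames (`ip`, `input`), each with chrom,
#'   start, end, value.
#' @export
simulate_chip_coverage <- function(genome,
                                   multipliers = chip_multipliers("wildtype"),
                                   config = genome$config, seed = NULL) {
  stopifnot(inherits(genome, "toy_genome"))
  if (any(multipliers < 0)) stop("enrichment multipliers must be >= 0")
  missing_roles <- setdiff(SIM_ROLES, names(multipliers))
  if (length(missing_roles))
    stop("multiplier missing for role: ", paste(missing_roles, collapse = ", "))
  bw <- config$chip_binwidth
  ann <- genome$annotations
  grids <- lapply(names(genome$chromosomes), function(chrom) {
    L <- nchar(genome$chromosomes[[chrom]])
    starts <- seq(0L, L - 1L, by = bw)
    ends <- pmin(starts + bw, L)
    mid <- (starts + ends) / 2
    role <- rep("background", length(starts))
    a <- ann[ann$chrom == chrom & ann$role != "hairpin_span", , drop = FALSE]
    for (r in c("gene", "satellite_array", "ATHILA_other", "ATHILA5")) {
      ar <- a[a$role == r, , drop = FALSE]
      for (k in seq_len(nrow(ar)))
        role[mid >= ar$start[k] & mid < ar$end[k]] <- r
    }
    data.frame(chrom = chrom, start = starts, end = ends, role = role,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, grids)
  seed <- seed %||% derive_seed(config$seed, "chip_coverage")
  with_seed(seed, {
    lambda <- config$chip_depth * (grid$end - grid$start) / bw
    input <- stats::rpois(nrow(grid), lambda)
    ip <- stats::rpois(nrow(grid), lambda * multipliers[grid$role])
    list(ip = data.frame(grid[c("chrom", "start", "end")], value = ip),
         input = data.frame(grid[c("chrom", "start", "end")], value = input))
  })
}
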