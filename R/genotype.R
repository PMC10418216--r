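SIM_ROLES <- c("satellite_array", "ATHILA5", "ATHILA_other", "gene",
               "background")
CONTEXTS <- c("CG", "CHG", "CHH")

#' Specify the methylation state of a genotype
#'
#' A genotype is a matrix of target methylation levels per (annotation role,
#' cytosine context), optionally modified by (i) hypermethylated loci that
#' gain methylation in all three contexts (the suppressor phenotype) and
#' (ii) an RNAi-hairpin restoration flag that raises CHG and CHH — never CG —
#' within the hairpin-homologous sub-span of every ATHILA5 copy, matching
#' RNA-directed (non-CG) methylation.
#'
#' @param name genotype label (also seeds this genotype's noise stream).
#' @param levels numeric matrix, rows = roles (`satellite_array`, `ATHILA5`,
#'   `ATHILA_other`, `gene`, `background`), columns = `CG`,`CHG`,`CHH`;
#'   values in `[0,1]`.
#' @param hyper_loci optional data.frame (chrom, start, end) of loci
#'   hypermethylated in all contexts.
#' @param hyper_levels per-context levels applied (as a floor) inside
#'   `hyper_loci`.
#' @param hairpin_restore logical; restore non-CG methylation at
#'   hairpin-homologous ATHILA5 spans.
#' @param hairpin_levels per-context floor applied under `hairpin_restore`;
#'   its CG entry must be `NA` (the hairpin never raises CG).
#' @return object of class `"genotype_spec"`.
#' @seealso [genotype_preset()] for the mutant panel used throughout.
#' @export
genotype_spec <- function(name, levels,
                          hyper_loci = NULL,
                          hyper_levels = c(CG = 0.85, CHG = 0.60, CHH = 0.40),
                          hairpin_restore = FALSE,
                          hairpin_levels = c(CG = NA, CHG = 0.55, CHH = 0.35)) {
  stopifnot(is.matrix(levels),
            all(CONTEXTS %in% colnames(levels)),
            !is.null(rownames(levels)))
  if (any(levels < 0 | levels > 1, na.rm = TRUE))
    stop("target methylation levels must lie in [0,1]")
  if (hairpin_restore && !is.na(hairpin_levels["CG"]))
    stop("hairpin restoration must not raise CG methylation")
  if (!is.null(hyper_loci))
    stopifnot(all(c("chrom", "start", "end") %in% names(hyper_loci)))
  structure(list(name = name, levels = levels[, CONTEXTS, drop = FALSE],
                 hyper_loci = hyper_loci, hyper_levels = hyper_levels,
                 hairpin_restore = hairpin_restore,
                 hairpin_levels = hairpin_levels),
            class = "genotype_spec")
}

#' @export
print.genotype_spec <- function(x, ...) {
  cat("genotype_spec:", x$name, "\n")
  print(round(x$levels, 3))
  if (!is.null(x$hyper_loci))
    cat("  hyper loci:", nrow(x$hyper_loci), "\n")
  if (x$hairpin_restore)
    cat("  hairpin restoration of CHG/CHH at ATHILA5\n")
  invisible(x)
}

# default level tables; heterochromatin heavily CG/CHG methylated in the
# methylated background, collapsed (CHH retained at satellites) when the
# maintenance remodeler is lost, and further CHH loss at elements when
# RdRP-dependent small RNAs are also lost
.levels_wildtype <- function() {
  rbind(satellite_array = c(0.92, 0.75, 0.10),
        ATHILA5         = c(0.90, 0.65, 0.12),
        ATHILA_other    = c(0.90, 0.65, 0.12),
        gene            = c(0.10, 0.02, 0.02),
        background      = c(0.20, 0.05, 0.05)) |>
    (\(m) { colnames(m) <- CONTEXTS; m })()
}

.levels_hypomethylated <- function() {
  rbind(satellite_array = c(0.03, 0.03, 0.10),
        ATHILA5         = c(0.05, 0.05, 0.03),
        ATHILA_other    = c(0.05, 0.05, 0.03),
        gene            = c(0.10, 0.02, 0.02),
        background      = c(0.15, 0.04, 0.04)) |>
    (\(m) { colnames(m) <- CONTEXTS; m })()
}

#' Genotype presets for the mutant panel
#'
#' * `"wildtype"`: methylated heterochromatin (also used for the RdRP triple
#'   mutant, whose methylation is intact).
#' * `"hypomethylated"`: the remodeler-mutant state — satellites lose CG and
#'   CHG methylation but retain CHH; elements additionally lose CHH.
#' * `"suppressor"`: hypomethylated plus ectopic hypermethylation in all
#'   three contexts at the supplied loci.
#' * `"hairpin_rescued"`: hypomethylated plus CHG/CHH (not CG) restoration at
#'   hairpin-homologous ATHILA5 spans.
#'
#' @param which preset name.
#' @param name optional label override (distinct labels give independent
#'   noise streams, e.g. for replicate suppressor lines).
#' @param hyper_loci loci for the `"suppressor"` preset.
#' @param ... passed to [genotype_spec()].
#' @return a `genotype_spec`.
#' @export
genotype_preset <- function(which = c("wildtype", "hypomethylated",
                                      "suppressor", "hairpin_rescued"),
                            name = NULL, hyper_loci = NULL, ...) {
  which <- match.arg(which)
  name <- name %||% which
  switch(which,
    wildtype = genotype_spec(name, .levels_wildtype(), ...),
    hypomethylated = genotype_spec(name, .levels_hypomethylated(), ...),
    suppressor = {
      if (is.null(hyper_loci))
        stop("suppressor preset needs hyper_loci")
      genotype_spec(name, .levels_hypomethylated(),
                    hyper_loci = hyper_loci, ...)
    },
    hairpin_rescued = genotype_spec(name, .levels_hypomethylated(),
                                    hairpin_restore = TRUE, ...))
}
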