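#' Default mis-segregation probabilities per genotype
#'
#' Point rates used by the cytology simulator; the severe phenotype arises
#' only when both the remodeler and all three RdRPs are lost, and is largely
#' rescued by the hairpin.
#' @return named numeric vector of per-cell mis-segregation probabilities.
#' @export
default_missegregation_rates <- function() {
  c(WT = 0, `rdr1;2` = 0, `rdr1;2;6` = 0, `rdr1;2 ddm1` = 0,
    `rdr1;2;6 ddm1` = 0.31, `rdr1;2;6 ddm1 hp5` = 0.03)
}

#' Simulate scored cytology records
#'
#' Produces one table of scored cells covering the assays the statistics
#' module consumes:
#' * anaphase cells (`stage == "anaphase"`, `assay == "lagging"`):
#'   `n_cells_scored` per genotype; a cell mis-segregates with the genotype's
#'   rate, and each event is assigned a chromosome identity — the focal
#'   chromosome with probability `chr5_bias`, otherwise uniform over the
#'   rest. Abnormal cells carry a FISH probe chromosome and a colocalization
#'   flag (`assay == "fish_attribution"`).
#' * prophase FISH nuclei (`assay == "cohesion"`): `n_nuclei_cohesion` per
#'   genotype with sister-chromatid dot counts in {1,2,3,4} drawn from the
#'   genotype's `dot_probs` row.
#' * chromocenter nuclei (`assay == "chromocenter"`): per-chromocenter DAPI
#'   intensities (semicolon-joined) plus whole-nucleus intensity, and paired
#'   H3K9me2/DAPI intensities; condensation scales with `condensation`.
#' * H3T3ph dots (`assay == "h3t3ph_dot"`): dot and nucleus areas.
#'
#' @param config a [simulation_config()].
#' @param rates named per-genotype mis-segregation probabilities in `[0,1]`.
#' @param chr5_bias probability a mis-segregation event involves the focal
#'   chromosome (in `[0,1]`).
#' @param chromosomes chromosome names (probe panel).
#' @param focal_chrom focal chromosome name.
#' @param dot_probs matrix (genotypes x 4) of dot-count probabilities; rows
#'   sum to 1. Default: cohered (mostly 2 dots) except severe genotypes.
#' @param condensation named per-genotype chromocenter condensation factor
#'   (fraction of nuclear signal concentrated in chromocenters).
#' @param n_nuclei_cohesion prophase nuclei scored per genotype.
#' @param n_dots_h3t3 H3T3ph dots measured per genotype.
#' @param seed optional seed override.
#' @return data.frame of cytology records; optional fields are `NA` where a
#'   record's assay does not measure them.
#' @export
simulate_cytology <- function(config,
                              rates = default_missegregation_rates(),
                              chr5_bias = 0.84,
                              chromosomes = paste0("Chr", 1:5),
                              focal_chrom = "Chr5",
                              dot_probs = NULL,
                              condensation = NULL,
                              n_nuclei_cohesion = 50L,
                              n_dots_h3t3 = 100L,
                              seed = NULL) {
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]")
  if (chr5_bias < 0 || chr5_bias > 1) stop("chr5_bias must lie in [0,1]")
  gts <- names(rates)
  if (is.null(dot_probs)) {
    dot_probs <- matrix(rep(c(0.02, 0.93, 0.04, 0.01), length(gts)),
                        nrow = length(gts), byrow = TRUE,
                        dimnames = list(gts, 1:4))
    severe <- rates >= 0.2
    dot_probs[severe, ] <- rep(c(0.05, 0.30, 0.40, 0.25), each = sum(severe))
  }
  if (is.null(condensation)) {
    condensation <- stats::setNames(rep(0.35, length(gts)), gts)
    condensation[rates >= 0.2] <- 0.12
  }
  seed <- seed %||% derive_seed(config$seed, "cytology")
  with_seed(seed, {
    rec <- list()
    blank <- function(n, genotype, stage, assay) data.frame(
      genotype = genotype, cell_id = NA_character_, stage = stage,
      assay = assay, n_lagging = NA_integer_,
      event_chromosome = NA_character_, fish_probe_chromosome = NA_character_,
      fish_colocalized = NA, fish_dot_count = NA_integer_,
      chromocenter_intensities = NA_character_, nucleus_intensity = NA_real_,
      h3k9me2_intensity = NA_real_, dapi_intensity = NA_real_,
      dot_area = NA_real_, nucleus_area = NA_real_,
      stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]

    for (g in gts) {
      # anaphase lagging-chromosome scoring
      n <- config$n_cells_scored
      a <- blank(n, g, "anaphase", "lagging")
      a$cell_id <- sprintf("%s_ana_%03d", g, seq_len(n))
      a$n_lagging <- stats::rbinom(n, 1L, rates[[g]])
      abn <- a$n_lagging >= 1L
      others <- setdiff(chromosomes, focal_chrom)
      ev <- ifelse(stats::runif(sum(abn)) < chr5_bias, focal_chrom,
                   sample(others, sum(abn), replace = TRUE))
      a$event_chromosome[abn] <- ev
      rec[[length(rec) + 1]] <- a

      # FISH attribution: abnormal cells assayed per probe chromosome
      if (rates[[g]] > 0) {
        for (probe in chromosomes) {
          m <- max(10L, round(config$n_cells_scored * rates[[g]]))
          f <- blank(m, g, "anaphase", "fish_attribution")
          f$cell_id <- sprintf("%s_fish_%s_%03d", g, probe, seq_len(m))
          f$n_lagging <- 1L
          f$fish_probe_chromosome <- probe
          ev <- ifelse(stats::runif(m) < chr5_bias, focal_chrom,
                       sample(others, m, replace = TRUE))
          f$event_chromosome <- ev
          f$fish_colocalized <- ev == probe
          rec[[length(rec) + 1]] <- f
        }
      }

      # prophase cohesion dot counts
      p <- blank(n_nuclei_cohesion, g, "prophase", "cohesion")
      p$cell_id <- sprintf("%s_coh_%03d", g, seq_len(n_nuclei_cohesion))
      p$fish_dot_count <- sample(1:4, n_nuclei_cohesion, replace = TRUE,
                                 prob = dot_probs[g, ])
      rec[[length(rec) + 1]] <- p

      # chromocenter + immunofluorescence measurements
      m <- config$n_chromocenters
      cc <- blank(m, g, "prophase", "chromocenter")
      cc$cell_id <- sprintf("%s_cc_%03d", g, seq_len(m))
      nuc <- stats::rgamma(m, shape = 50, rate = 0.05)
      k <- condensation[[g]]
      ints <- lapply(seq_len(m), function(i) {
        w <- stats::rgamma(9, shape = 4, rate = 1)
        round(nuc[i] * k * w / sum(w), 2)
      })
      cc$chromocenter_intensities <- vapply(ints, paste, "", collapse = ";")
      cc$nucleus_intensity <- round(nuc, 2)
      cc$dapi_intensity <- round(nuc * k / 9, 2)
      cc$h3k9me2_intensity <- round(cc$dapi_intensity *
        stats::rgamma(m, shape = 40, rate = 40 / (0.4 + 1.2 * k)), 2)
      rec[[length(rec) + 1]] <- cc

      # H3T3ph dot sizes relative to nucleus
      h <- blank(n_dots_h3t3, g, "prophase", "h3t3ph_dot")
      h$cell_id <- sprintf("%s_h3t3_%03d", g, seq_len(n_dots_h3t3))
      h$nucleus_area <- stats::rgamma(n_dots_h3t3, shape = 60, rate = 0.6)
      h$dot_area <- h$nucleus_area * 0.01 * (0.5 + 2.5 * k) *
        stats::rgamma(n_dots_h3t3, shape = 10, rate = 10)
      rec[[length(rec) + 1]] <- h
    }
    out <- do.call(rbind, rec)
    rownames(out) <- NULL
    out
  })
}

#' Write / read cytology record tables as TSV
#'
#' @param records cytology data.frame (see [simulate_cytology()]).
#' @param path file path.
#' @return `path` invisibly, or the records data.frame.
#' @export
write_cytology <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cytology
#' @export
read_cytology <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE)
}
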