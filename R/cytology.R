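anaphase_counts <- function(records, genotype) {
  r <- records[records$stage == "anaphase" & records$genotype == genotype &
                 records$assay == "lagging" & !is.na(records$n_lagging), ,
               drop = FALSE]
  if (!nrow(r)) stop("no anaphase records for genotype ", genotype)
  c(abnormal = sum(r$n_lagging >= 1L), n = nrow(r))
}

#' Mitotic mis-segregation rate with exact confidence interval
#'
#' A cell mis-segregates when it shows at least one lagging chromosome; the
#' rate is the fraction of scored anaphase cells with an event, with a
#' Clopper-Pearson (exact binomial) 95% CI.
#'
#' @param records cytology records (see [simulate_cytology()] for the
#'   layout).
#' @param genotype genotype label to score.
#' @param conf_level CI confidence level.
#' @return list: rate, n, abnormal, ci (length-2 vector).
#' @examples
#' rec <- data.frame(genotype = "m", stage = "anaphase", assay = "lagging",
#'                   n_lagging = c(rep(1, 31), rep(0, 69)))
#' missegregation_rate(rec, "m")$rate  # 0.31
#' @export
missegregation_rate <- function(records, genotype, conf_level = 0.95) {
  k <- anaphase_counts(records, genotype)
  bt <- stats::binom.test(k[["abnormal"]], k[["n"]],
                          conf.level = conf_level)
  list(rate = k[["abnormal"]] / k[["n"]], n = k[["n"]],
       abnormal = k[["abnormal"]],
       ci = as.numeric(bt$conf.int))
}

#' Compare mis-segregation rates of two genotypes
#'
#' Two-sided Fisher's exact test on the 2x2 abnormal/normal table.
#'
#' @param records cytology records.
#' @param genotype_a,genotype_b genotype labels (must differ).
#' @return list: p_value, rate_a, rate_b, rate_difference, table.
#' @export
compare_rates <- function(records, genotype_a, genotype_b) {
  if (identical(genotype_a, genotype_b))
    stop("genotypes to compare must differ")
  ka <- anaphase_counts(records, genotype_a)
  kb <- anaphase_counts(records, genotype_b)
  tab <- rbind(a = c(ka[["abnormal"]], ka[["n"]] - ka[["abnormal"]]),
               b = c(kb[["abnormal"]], kb[["n"]] - kb[["abnormal"]]))
  ft <- stats::fisher.test(tab)
  list(p_value = ft$p.value,
       rate_a = ka[["abnormal"]] / ka[["n"]],
       rate_b = kb[["abnormal"]] / kb[["n"]],
       rate_difference = ka[["abnormal"]] / ka[["n"]] -
         kb[["abnormal"]] / kb[["n"]],
       table = tab)
}

#' Attribute mis-segregation events to chromosomes by FISH colocalization
#'
#' Per probe chromosome, the proportion of abnormal cells whose
#' mis-segregating chromosome colocalizes with the probe, with an exact CI.
#' Probes are separate experiments, so proportions need not sum to 1.
#'
#' @param records cytology records with `assay == "fish_attribution"`.
#' @param genotype optional genotype filter.
#' @return data.frame: chromosome, colocalized, n, proportion, ci_lo, ci_hi;
#'   probes with no abnormal cells get `NA` proportion and are flagged in
#'   `attr(, "undefined_probes")`.
#' @export
chromosome_attribution <- function(records, genotype = NULL) {
  r <- records[records$assay == "fish_attribution" &
                 !is.na(records$fish_probe_chromosome), , drop = FALSE]
  if (!is.null(genotype)) r <- r[r$genotype == genotype, , drop = FALSE]
  probes <- sort(unique(r$fish_probe_chromosome))
  rows <- lapply(probes, function(p) {
    rp <- r[r$fish_probe_chromosome == p & r$n_lagging >= 1L, , drop = FALSE]
    n <- nrow(rp)
    if (!n)
      return(data.frame(chromosome = p, colocalized = 0L, n = 0L,
                        proportion = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, stringsAsFactors = FALSE))
    x <- sum(rp$fish_colocalized)
    ci <- as.numeric(stats::binom.test(x, n)$conf.int)
    data.frame(chromosome = p, colocalized = x, n = n, proportion = x / n,
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "undefined_probes") <- out$chromosome[is.na(out$proportion)]
  out
}

#' Sister-chromatid cohesion dot classes
#'
#' Histogram of prophase FISH dot counts and the fraction of nuclei with
#' reduced cohesion (3 or 4 dots); single-dot nuclei (unresolved sisters)
#' are reported separately as unclassified.
#'
#' @param records cytology records with `assay == "cohesion"`.
#' @param genotype genotype label.
#' @return list: histogram (named counts over 1..4), n, reduced_fraction,
#'   n_unclassified.
#' @export
cohesion_classes <- function(records, genotype) {
  r <- records[records$assay == "cohesion" & records$genotype == genotype &
                 !is.na(records$fish_dot_count), , drop = FALSE]
  if (!nrow(r)) stop("no cohesion records for genotype ", genotype)
  if (any(!r$fish_dot_count %in% 1:4))
    stop("dot counts must lie in {1,2,3,4}")
  h <- table(factor(r$fish_dot_count, levels = 1:4))
  n <- nrow(r)
  list(histogram = stats::setNames(as.integer(h), names(h)), n = n,
       reduced_fraction = sum(r$fish_dot_count >= 3L) / n,
       n_unclassified = sum(r$fish_dot_count == 1L))
}

parse_intensities <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Fraction of nuclear signal concentrated in chromocenters
#'
#' Per record, the sum of chromocenter intensities divided by whole-nucleus
#' intensity — the condensation readout of DAPI-stained nuclei.
#'
#' @param chromocenter_intensities numeric vector, or semicolon-joined
#'   string as stored in cytology tables (empty = no chromocenters, giving
#'   fraction 0).
#' @param nucleus_intensity positive scalar.
#' @return proportion in `[0, 1]`.
#' @export
chromocenter_fraction <- function(chromocenter_intensities,
                                  nucleus_intensity) {
  if (is.na(nucleus_intensity) || nucleus_intensity <= 0)
    stop("nucleus_intensity must be positive")
  cc <- parse_intensities(chromocenter_intensities)
  if (any(cc < 0)) stop("intensities must be non-negative")
  s <- sum(cc)
  if (s > nucleus_intensity)
    stop("chromocenter sum exceeds nucleus intensity ",
         "(segmentation inconsistency)")
  s / nucleus_intensity
}

#' Group summary of chromocenter fractions
#'
#' Five-number boxplot summaries of per-record chromocenter fractions per
#' genotype.
#'
#' @param records cytology records with `assay == "chromocenter"`.
#' @return data.frame: genotype, min, q1, median, q3, max, n.
#' @export
chromocenter_summary <- function(records) {
  r <- records[records$assay == "chromocenter", , drop = FALSE]
  rows <- lapply(split(r, r$genotype), function(rg) {
    fr <- vapply(seq_len(nrow(rg)), function(i)
      chromocenter_fraction(rg$chromocenter_intensities[i],
                            rg$nucleus_intensity[i]), numeric(1))
    f <- stats::fivenum(fr)
    data.frame(genotype = rg$genotype[1], min = f[1], q1 = f[2],
               median = f[3], q3 = f[4], max = f[5], n = length(fr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Immunofluorescence ratios
#'
#' `kind = "H3K9me2/DAPI"`: heterochromatin-mark intensity relative to DNA
#' stain per chromocenter. `kind = "H3T3ph_dot_size"`: phospho-mark dot area
#' relative to nucleus area.
#'
#' @param records cytology records.
#' @param kind ratio kind.
#' @return numeric vector of ratios (scale-invariant: common rescaling of
#'   numerator and denominator leaves them unchanged).
#' @export
if_ratio <- function(records, kind = c("H3K9me2/DAPI", "H3T3ph_dot_size")) {
  kind <- match.arg(kind)
  if (kind == "H3K9me2/DAPI") {
    num <- records$h3k9me2_intensity; den <- records$dapi_intensity
  } else {
    num <- records$dot_area; den <- records$nucleus_area
  }
  keep <- !is.na(num) & !is.na(den)
  num <- num[keep]; den <- den[keep]
  if (any(den <= 0)) stop("zero or negative denominator")
  num / den
}

#' Fertility class from seed availability and silique length
#'
#' A plant with 1-10 seeds overall is Sterile regardless of silique lengths.
#' Otherwise the class follows the plant's representative (median) primary
#' silique length using half-open bins `[3,5) [5,7) [7,9) [9,11) [11,Inf)`
#' mm with the corresponding approximate seeds-per-silique bands; lengths
#' below 3 mm fall in the Sterile class.
#'
#' @param silique_lengths_mm positive numeric vector of silique lengths.
#' @param seeds_per_plant optional total seed count.
#' @return list: class (length bin label or `"Sterile"`), seeds_band,
#'   median_length_mm.
#' @examples
#' fertility_class(8)$seeds_band    # "10-15 seeds / silique"
#' fertility_class(12)$seeds_band   # "> 20 seeds / silique"
#' @export
fertility_class <- function(silique_lengths_mm = NULL,
                            seeds_per_plant = NULL) {
  if (is.null(silique_lengths_mm) && is.null(seeds_per_plant))
    stop("need silique lengths or a seed count")
  if (!is.null(silique_lengths_mm) && any(silique_lengths_mm <= 0))
    stop("silique lengths must be positive")
  med <- if (length(silique_lengths_mm))
    stats::median(silique_lengths_mm) else NA_real_
  if (!is.null(seeds_per_plant) && seeds_per_plant <= 10)
    return(list(class = "Sterile", seeds_band = "1-10 seeds / plant",
                median_length_mm = med))
  if (is.na(med)) stop("need silique lengths for a fertile plant")
  bins <- c(3, 5, 7, 9, 11)
  bands <- c("1-5 seeds / silique", "5-10 seeds / silique",
             "10-15 seeds / silique", "15-20 seeds / silique",
             "> 20 seeds / silique")
  i <- findInterval(med, bins)
  if (i == 0)
    return(list(class = "Sterile", seeds_band = "1-10 seeds / plant",
                median_length_mm = med))
  cls <- c("3-5 mm", "5-7 mm", "7-9 mm", "9-11 mm", "> 11 mm")[i]
  list(class = cls, seeds_band = bands[i], median_length_mm = med)
}
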