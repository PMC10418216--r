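#' Bulked-segregant SNP scan over pooled allele frequencies
#'
#' For a recessive suppressor mutation segregating in selfed progeny of a
#' heterozygous parent, the causal allele frequency is 1 in the suppressor
#' pool and 1/3 in the phenotypically normal pool (2/3 heterozygous, 1/3
#' wild-type among non-suppressors), so the per-SNP allele-frequency
#' difference `delta = AF_suppressor - AF_nonsuppressor` peaks at 2/3 at the
#' causal site and decays with linkage. The scan computes delta per SNP,
#' averages it on a fixed window grid, and reports the peak region (the
#' contiguous windows around the maximum whose mean delta stays above
#' `peak_frac` of the maximum).
#'
#' @param obs SNP observation data.frame: chrom, pos, ref, alt, ad_sup,
#'   dp_sup, ad_non, dp_non (allele depths and total depths per pool).
#' @param window grid width in bp for the windowed delta profile.
#' @param peak_frac fraction of the peak mean defining the peak region.
#' @return list with `snps` (obs plus af_sup, af_non, delta), `profile`
#'   (chrom, start, end, n_snps, mean_delta), and `peak` (one region row).
#'   Zero-depth SNPs are skipped with a warning.
#' @export
bsa_snp_scan <- function(obs, window = 2000L, peak_frac = 0.5) {
  stopifnot(all(c("chrom", "pos", "ad_sup", "dp_sup", "ad_non", "dp_non")
                %in% names(obs)))
  if (any(obs$ad_sup > obs$dp_sup | obs$ad_non > obs$dp_non))
    stop("allele counts exceed pool depths")
  zero <- obs$dp_sup == 0 | obs$dp_non == 0
  if (any(zero)) {
    warning(sum(zero), " SNP(s) with zero pool depth skipped")
    obs <- obs[!zero, , drop = FALSE]
  }
  obs$af_sup <- obs$ad_sup / obs$dp_sup
  obs$af_non <- obs$ad_non / obs$dp_non
  obs$delta <- obs$af_sup - obs$af_non
  win <- obs$pos %/% window
  key <- paste(obs$chrom, win, sep = "\r")
  ks <- sort(unique(key))
  parts <- do.call(rbind, strsplit(ks, "\r", fixed = TRUE))
  profile <- data.frame(
    chrom = parts[, 1],
    start = as.integer(parts[, 2]) * as.integer(window),
    stringsAsFactors = FALSE)
  profile$end <- profile$start + as.integer(window)
  profile$n_snps <- as.integer(tapply(obs$delta, key, length)[ks])
  profile$mean_delta <- as.numeric(tapply(obs$delta, key, mean)[ks])
  profile <- profile[order(profile$chrom, profile$start), , drop = FALSE]
  rownames(profile) <- NULL

  imax <- which.max(profile$mean_delta)
  thr <- peak_frac * profile$mean_delta[imax]
  on_chrom <- which(profile$chrom == profile$chrom[imax])
  pos_in <- match(imax, on_chrom)
  lo <- pos_in
  while (lo > 1 && profile$mean_delta[on_chrom[lo - 1]] >= thr &&
         profile$start[on_chrom[lo]] - profile$start[on_chrom[lo - 1]] ==
           window) lo <- lo - 1
  hi <- pos_in
  while (hi < length(on_chrom) &&
         profile$mean_delta[on_chrom[hi + 1]] >= thr &&
         profile$start[on_chrom[hi + 1]] - profile$start[on_chrom[hi]] ==
           window) hi <- hi + 1
  peak <- data.frame(chrom = profile$chrom[imax],
                     start = profile$start[on_chrom[lo]],
                     end = profile$end[on_chrom[hi]],
                     peak_delta = profile$mean_delta[imax],
                     stringsAsFactors = FALSE)
  list(snps = obs, profile = profile, peak = peak)
}

#' Simulate pooled SNP observations around one causal suppressor mutation
#'
#' EMS-like SNPs are scattered uniformly over the genome; the causal SNP has
#' true pooled allele frequencies (1, 1/3) and linked SNPs interpolate
#' linearly toward the unlinked frequencies (0.5, 0.5) over `linkage_bp`.
#' Pool depths are Poisson around `depth_mean`, allele depths Binomial.
#'
#' @param genome a `toy_genome`.
#' @param config a [simulation_config()]; pool sizes bound the allele counts.
#' @param causal data.frame/list with chrom, pos of the causal SNP; defaults
#'   to the focal-chromosome centromere midpoint.
#' @param n_snps total SNPs simulated.
#' @param linkage_bp linkage decay scale in bp.
#' @param depth_mean mean sequencing depth per pool.
#' @param seed optional seed override.
#' @return an observation data.frame as consumed by [bsa_snp_scan()], with
#'   the causal SNP included and flagged by the `causal` column.
#' @export
simulate_bsa_observations <- function(genome, config, causal = NULL,
                                      n_snps = 200L, linkage_bp = 10000,
                                      depth_mean = 50, seed = NULL) {
  lens <- config$chrom_lengths
  if (is.null(causal)) {
    cen <- genome$centromeres
    fc <- cen[cen$chrom == genome$focal_chrom, ]
    causal <- list(chrom = fc$chrom, pos = as.integer((fc$start + fc$end) / 2))
  }
  seed <- seed %||% derive_seed(config$seed, "bsa_snps")
  with_seed(seed, {
    chrom <- sample(names(lens), n_snps, replace = TRUE,
                    prob = as.numeric(lens))
    pos <- floor(stats::runif(n_snps) * lens[chrom])
    chrom <- c(chrom, causal$chrom)
    pos <- as.integer(c(pos, causal$pos))
    is_causal <- c(rep(FALSE, n_snps), TRUE)
    d <- ifelse(chrom == causal$chrom, abs(pos - causal$pos), Inf)
    link <- pmax(0, 1 - d / linkage_bp)
    af_sup <- 0.5 + link * (1 - 0.5)
    af_non <- 0.5 + link * (1 / 3 - 0.5)
    af_sup[is_causal] <- 1; af_non[is_causal] <- 1 / 3
    n <- length(pos)
    dp_sup <- stats::rpois(n, depth_mean)
    dp_non <- stats::rpois(n, depth_mean)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               ad_sup = stats::rbinom(n, dp_sup, af_sup), dp_sup = dp_sup,
               ad_non = stats::rbinom(n, dp_non, af_non), dp_non = dp_non,
               causal = is_causal, stringsAsFactors = FALSE)
  })
}

#' Read a VCF-like pooled SNP table
#'
#' Tab-separated with header `CHROM POS REF ALT AD_SUP DP_SUP AD_NON DP_NON`
#' (`POS` 1-based, converted to the package's 0-based convention).
#'
#' @param path file path.
#' @return observation data.frame for [bsa_snp_scan()].
#' @export
read_snp_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("CHROM", "POS", "REF", "ALT", "AD_SUP", "DP_SUP", "AD_NON",
            "DP_NON")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  data.frame(chrom = df$CHROM, pos = df$POS - 1L, ref = df$REF,
             alt = df$ALT, ad_sup = df$AD_SUP, dp_sup = df$DP_SUP,
             ad_non = df$AD_NON, dp_non = df$DP_NON, stringsAsFactors = FALSE)
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

count_motif_over <- function(seq, motif, offset) {
  # occurrences (either strand) of motif overlapping 0-based position offset
  motifs <- unique(c(motif, revcomp(motif)))
  total <- 0L
  n <- nchar(seq); m <- nchar(motif)
  for (mo in motifs) {
    starts <- seq_len(max(0L, n - m + 1L)) - 1L      # 0-based starts
    starts <- starts[starts <= offset & offset < starts + m]
    for (s in starts)
      if (substr(seq, s + 1L, s + m) == mo) total <- total + 1L
  }
  total
}

#' Classify a SNP as a candidate CAPS marker
#'
#' Compares occurrences of a restriction-enzyme recognition motif (either
#' strand) overlapping the SNP position between the reference and alternate
#' sequence: more occurrences with the alternate allele means the SNP
#' creates a cut site, fewer means it destroys one, equal counts are
#' uninformative for digestion-based scoring.
#'
#' @param sequence flanking sequence over `{A,C,G,T}` containing the SNP.
#' @param offset 0-based offset of the SNP within `sequence`.
#' @param ref,alt reference and alternate base.
#' @param motif recognition motif over `{A,C,G,T}` (e.g. `"TTAATTAA"`).
#' @return one of `"creates_site"`, `"destroys_site"`, `"uninformative"`.
#' @examples
#' caps_check("TTAATTGA", 6, "G", "A", "TTAATTAA")  # creates_site
#' @export
caps_check <- function(sequence, offset, ref, alt, motif) {
  sequence <- toupper(sequence); motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}")
  if (offset < 0 || offset >= nchar(sequence))
    stop("offset outside sequence")
  at <- substr(sequence, offset + 1L, offset + 1L)
  if (at != toupper(ref))
    stop("reference base mismatch at offset ", offset, ": sequence has ",
         at, ", expected ", ref)
  alt_seq <- sequence
  substr(alt_seq, offset + 1L, offset + 1L) <- toupper(alt)
  n_ref <- count_motif_over(sequence, motif, offset)
  n_alt <- count_motif_over(alt_seq, motif, offset)
  if (n_alt > n_ref) "creates_site"
  else if (n_alt < n_ref) "destroys_site"
  else "uninformative"
}
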