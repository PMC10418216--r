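test_that("pooled profiles average lines with equal weight", {
  calls1 <- simulate_methylome(tiny_genome, genotype_preset("wildtype"),
                               tiny_cfg, tiny_template)
  # identical lines: group profile equals the single-line profile
  p <- pool_profiles(list(a = calls1, b = calls1),
                     c("fertile", "sterile"), width = 2000)
  single <- window_methylation(calls1, 2000)
  expect_equal(p$fertile$total_level, single$total_level)
  expect_equal(p$sterile$total_level, single$total_level)
  expect_error(pool_profiles(list(a = calls1), "fertile"), "empty")
})

test_that("pooling equals brute-force per-window recomputation", {
  lines <- lapply(1:4, function(i)
    simulate_line_methylome(tiny_genome,
      simulate_recombinant_lines(tiny_genome, tiny_cfg, seed = i)[[1]],
      tiny_cfg, tiny_template, seed = 100 + i))
  ph <- c("fertile", "fertile", "sterile", "sterile")
  pools <- pool_profiles(lines, ph, width = 2000)
  # brute force: mean of the two per-line window levels
  for (grp in c("fertile", "sterile")) {
    idx <- which(ph == grp)
    p1 <- window_methylation(lines[[idx[1]]], 2000)
    p2 <- window_methylation(lines[[idx[2]]], 2000)
    stopifnot(identical(p1$start, p2$start))
    want <- rowMeans(cbind(p1$total_level, p2$total_level))
    expect_equal(pools[[grp]]$total_level, want)
  }
  # two lines with window levels 0.2 and 0.6 average to 0.4
  mk <- function(lv) data.frame(chrom = "c", pos = c(1, 3), strand = "+",
                                context = "CG", n_meth = as.integer(lv * 10),
                                n_total = 10L)
  p <- pool_profiles(list(mk(0.2), mk(0.6), mk(0.5)),
                     c("fertile", "fertile", "sterile"), width = 100)
  expect_equal(p$fertile$level_CG, 0.4)
})

test_that("linked-region scan ranks the hypomethylated linked run first", {
  mkp <- function(tot, width = 5000L) {
    n <- length(tot)
    out <- data.frame(chrom = "Chr5", start = (seq_len(n) - 1L) * width,
                      end = seq_len(n) * width, level_CG = NA, level_CHG = NA,
                      level_CHH = NA, total_level = tot,
                      stringsAsFactors = FALSE)
    attr(out, "width") <- width; attr(out, "grid_origin") <- 0L
    out
  }
  # null: identical pools give no candidate
  f <- mkp(rep(1.5, 10))
  expect_identical(nrow(linked_region_scan(f, f)), 0L)
  # single window just below delta_min is excluded
  s <- mkp(c(rep(1.5, 4), 1.31, rep(1.5, 5)))
  expect_identical(nrow(linked_region_scan(f, s, delta_min = 0.2)), 0L)
  s2 <- mkp(c(rep(1.5, 4), 1.2, 1.1, rep(1.5, 4)))
  cand <- linked_region_scan(f, s2, delta_min = 0.2)
  expect_identical(cand$start, 20000L)
  expect_identical(cand$end, 30000L)
  expect_equal(cand$mean_delta, 0.35)
})

test_that("marker epigenotyping applies the McrBC-style thresholds", {
  mk <- function(level) data.frame(chrom = "c", pos = 1000L, strand = "+",
                                   context = "CG",
                                   n_meth = as.integer(level * 100),
                                   n_total = 100L)
  markers <- data.frame(chrom = "c", pos = 1000L)
  expect_identical(epigenotype_markers(mk(0.05), markers)$call,
                   "ddm1_derived")
  expect_identical(epigenotype_markers(mk(0.8), markers)$call, "WT_derived")
  expect_identical(epigenotype_markers(mk(0.35), markers)$call, "ambiguous")
  # uncovered marker is ambiguous and flagged
  far <- data.frame(chrom = "c", pos = 90000L)
  out <- epigenotype_markers(mk(0.05), far)
  expect_identical(out$call, "ambiguous")
  expect_false(out$covered)
})

mk_calls <- function(markers, calls) {
  data.frame(chrom = "Chr5", pos = markers, call = calls,
             evidence = ifelse(calls == "ddm1_derived", 0.05, 0.9),
             covered = TRUE, stringsAsFactors = FALSE)
}

test_that("interval mapping intersects sterile spans and subtracts fertile spans", {
  markers <- c(5000, 15000, 25000, 35000, 45000)
  st <- mk_calls(markers, c("WT_derived", "ddm1_derived", "ddm1_derived",
                            "WT_derived", "WT_derived"))
  fe <- mk_calls(markers, c("ddm1_derived", "WT_derived", "WT_derived",
                            "WT_derived", "WT_derived"))
  res <- map_interval(list(L1 = st, L2 = fe),
                      c(L1 = "sterile", L2 = "fertile"),
                      "Chr5", 50000)
  expect_identical(res$status, "consistent")
  # sterile span taken expansively out to the flanking discordant markers,
  # fertile span conservatively (its single ddm1 marker)
  expect_identical(res$interval$start, 5001L)
  expect_identical(res$interval$end, 35000L)
  # adding a fertile line ddm1-derived on the left half narrows it
  fe2 <- mk_calls(markers, c("ddm1_derived", "ddm1_derived", "WT_derived",
                             "WT_derived", "WT_derived"))
  res2 <- map_interval(list(L1 = st, L2 = fe, L3 = fe2),
                       c(L1 = "sterile", L2 = "fertile", L3 = "fertile"),
                       "Chr5", 50000)
  expect_identical(res2$status, "consistent")
  expect_gte(res2$interval$start, res$interval$start)
  expect_lte(res2$interval$end, res$interval$end)
  expect_lt(res2$interval$end - res2$interval$start,
            res$interval$end - res$interval$start)
  # a fertile line ddm1-derived across the whole sterile candidate region
  # forces a contradiction
  fe_all <- mk_calls(markers, rep("ddm1_derived", 5))
  res3 <- map_interval(list(L1 = st, L2 = fe_all),
                       c(L1 = "sterile", L2 = "fertile"),
                       "Chr5", 50000)
  expect_identical(res3$status, "inconsistent")
  expect_gt(length(res3$violating_lines), 0)
})

test_that("mapped interval always contains the planted locus on consistent panels", {
  causative <- {
    src <- hairpin_of(std_genome)$source
    data.frame(chrom = src$chrom, start = src$start, end = src$end)
  }
  # markers sit in the pericentromeric satellite array, where the
  # methylated/hypomethylated contrast (and hence McrBC scoring) is crisp
  markers <- data.frame(chrom = "Chr5",
                        pos = seq(15500, 34500, by = 1000))
  hits <- 0; n_used <- 0
  for (r in 1:10) {
    mos <- simulate_recombinant_lines(std_genome, std_cfg, causative,
                                      seed = 5000 + r)
    ph <- vapply(mos, `[[`, "", "phenotype")
    if (length(unique(ph)) < 2) next
    mcs <- lapply(mos, function(m) {
      calls <- simulate_line_methylome(std_genome, m, std_cfg, std_template,
                                       seed = derive_seed(r, m$line_id))
      epigenotype_markers(calls, markers)
    })
    names(mcs) <- vapply(mos, `[[`, "", "line_id")
    names(ph) <- names(mcs)
    res <- map_interval(mcs, ph, "Chr5", 50000)
    if (res$status != "consistent") next
    n_used <- n_used + 1
    ov <- sum(interval_overlap(res$interval$start, res$interval$end,
                               causative$start, causative$end))
    hits <- hits + (ov == causative$end - causative$start)
  }
  expect_gt(n_used, 2)
  expect_identical(hits, n_used)  # soundness: never excludes the locus
})

test_that("BSA delta allele frequencies follow the recessive pool design", {
  obs <- data.frame(chrom = "Chr5", pos = c(1000L, 2000L),
                    ref = "G", alt = "A",
                    ad_sup = c(30L, 15L), dp_sup = c(30L, 30L),
                    ad_non = c(20L, 30L), dp_non = c(60L, 60L))
  res <- bsa_snp_scan(obs, window = 10000)
  expect_equal(res$snps$delta[1], 1 - 1 / 3)
  expect_equal(res$snps$delta[2], 0)
  # antisymmetric under pool swap
  swapped <- obs
  swapped[c("ad_sup", "dp_sup", "ad_non", "dp_non")] <-
    obs[c("ad_non", "dp_non", "ad_sup", "dp_sup")]
  expect_equal(bsa_snp_scan(swapped, window = 10000)$snps$delta,
               -res$snps$delta)
  # zero-depth SNPs skipped with a warning
  obs0 <- rbind(obs, data.frame(chrom = "Chr5", pos = 3000L, ref = "C",
                                alt = "T", ad_sup = 0L, dp_sup = 0L,
                                ad_non = 1L, dp_non = 10L))
  expect_warning(r0 <- bsa_snp_scan(obs0, window = 10000), "skipped")
  expect_identical(nrow(r0$snps), 2L)
})

test_that("the BSA peak window contains the planted causal SNP", {
  hits <- vapply(1:20, function(r) {
    cfg <- simulation_config(seed = 900 + r)
    obs <- simulate_bsa_observations(std_genome, cfg)
    causal <- obs[obs$causal, ]
    peak <- bsa_snp_scan(obs[!names(obs) %in% "causal"])$peak
    peak$chrom == causal$chrom && causal$pos >= peak$start &&
      causal$pos < peak$end
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("CAPS classification detects restriction-site gain and loss", {
  # the PacI recognition site TTAATTAA is created by the centromeric G-to-A
  # transition
  expect_identical(caps_check("TTAATTGA", 6, "G", "A", "TTAATTAA"),
                   "creates_site")
  expect_identical(caps_check("TTAATTAA", 6, "A", "G", "TTAATTAA"),
                   "destroys_site")
  expect_identical(caps_check("GGGGCGGGG", 4, "C", "T", "TTAATTAA"),
                   "uninformative")
  # palindromic motif: classification identical on reverse complement
  s <- "CCTTAATTGACC"
  rc <- revcomp_str(s)
  expect_identical(caps_check(s, 8, "G", "A", "TTAATTAA"),
                   caps_check(rc, nchar(s) - 1 - 8, "C", "T", "TTAATTAA"))
  expect_error(caps_check("TTAATTGA", 6, "C", "A", "TTAATTAA"), "mismatch")
})

test_that("VCF-like SNP tables are read with the pooled depth columns", {
  f <- tempfile()
  writeLines(c("CHROM\tPOS\tREF\tALT\tAD_SUP\tDP_SUP\tAD_NON\tDP_NON",
               "Chr5\t10484\tG\tA\t30\t30\t20\t60"), f)
  obs <- read_snp_table(f)
  expect_identical(obs$pos, 10483L)
  expect_equal(bsa_snp_scan(obs, window = 1000)$snps$delta, 2 / 3)
  writeLines("CHROM\tPOS", f)
  expect_error(read_snp_table(f), "missing columns")
})
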