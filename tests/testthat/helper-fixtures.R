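# shared fixtures: one standard toy genome + template, built once per run
std_cfg <- simulation_config(seed = 101)
std_genome <- build_toy_genome(std_cfg)
std_template <- methylome_template(std_genome)
std_lens <- vapply(std_genome$chromosomes, nchar, integer(1))

# a smaller genome for cheap repeated simulation
tiny_cfg <- simulation_config(
  seed = 7, chrom_lengths = stats::setNames(rep(12000L, 5), paste0("Chr", 1:5)),
  focal_chrom = "Chr5", coverage_mean = 20)
tiny_genome <- build_toy_genome(tiny_cfg, element_length = 600L,
                                gene_length = 400L)
tiny_template <- methylome_template(tiny_genome)

# independent context oracle: perl lookahead motif scan on the sequence and
# its reverse complement with mirrored coordinates
oracle_contexts <- function(seq) {
  n <- nchar(seq)
  scan_plus <- function(s) {
    hit <- function(pat) {
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1) integer(0) else as.integer(m) - 1L
    }
    list(CG = hit("(?=CG)"), CHG = hit("(?=C[ACT]G)"),
         CHH = hit("(?=C[ACT][ACT])"))
  }
  rc <- chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  p <- scan_plus(seq)
  m <- scan_plus(rc)
  mirror <- function(j) n - 1L - j
  plus_all <- which(strsplit(seq, "")[[1]] == "C") - 1L
  minus_all <- which(strsplit(seq, "")[[1]] == "G") - 1L
  df <- rbind(
    data.frame(pos = plus_all, strand = "+",
               context = ifelse(plus_all %in% p$CG, "CG",
                         ifelse(plus_all %in% p$CHG, "CHG",
                         ifelse(plus_all %in% p$CHH, "CHH",
                                "undetermined")))),
    data.frame(pos = minus_all, strand = "-",
               context = ifelse(minus_all %in% mirror(m$CG), "CG",
                         ifelse(minus_all %in% mirror(m$CHG), "CHG",
                         ifelse(minus_all %in% mirror(m$CHH), "CHH",
                                "undetermined")))))
  df <- df[order(df$pos, df$strand), ]
  rownames(df) <- NULL
  df
}

# brute-force per-window recomputation of methylation levels
oracle_window <- function(calls, width) {
  key <- paste(calls$chrom, calls$pos %/% width)
  res <- lapply(split(calls, key), function(d) {
    lv <- sapply(c("CG", "CHG", "CHH"), function(ctx) {
      dd <- d[d$context == ctx, ]
      if (!nrow(dd)) NA_real_ else sum(dd$n_meth) / sum(dd$n_total)
    })
    data.frame(chrom = d$chrom[1], start = (d$pos[1] %/% width) * width,
               level_CG = lv[["CG"]], level_CHG = lv[["CHG"]],
               level_CHH = lv[["CHH"]],
               total_level = sum(lv, na.rm = TRUE))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# two-sided Fisher p by direct hypergeometric enumeration
oracle_fisher_p <- function(a, n1, b, n2) {
  m <- a + b
  ks <- max(0, m - n2):min(n1, m)
  pr <- stats::dhyper(ks, n1, n2, m)
  p_obs <- stats::dhyper(a, n1, n2, m)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# anaphase scoring fixture: `abnormal` lagging cells out of `n`
ana_records <- function(genotype, abnormal, n) {
  data.frame(genotype = genotype, stage = "anaphase", assay = "lagging",
             n_lagging = c(rep(1L, abnormal), rep(0L, n - abnormal)),
             stringsAsFactors = FALSE)
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
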