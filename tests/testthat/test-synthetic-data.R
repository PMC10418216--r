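test_that("toy genome is deterministic, annotated and well-formed", {
  g1 <- build_toy_genome(simulation_config(seed = 1))
  g2 <- build_toy_genome(simulation_config(seed = 1))
  expect_identical(g1$chromosomes, g2$chromosomes)
  expect_identical(g1$annotations, g2$annotations)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  g3 <- build_toy_genome(simulation_config(seed = 2), n_athila5 = 3)
  ann <- g3$annotations
  expect_identical(sum(ann$role == "ATHILA5" &
                         ann$chrom == g3$focal_chrom), 3L)
  # hairpin span contained in its source element
  hp <- hairpin_of(g3)
  expect_true(hp$span$start >= hp$source$start &&
                hp$span$end <= hp$source$end)
  # annotations inside chromosomes; intervals half-open and non-negative
  lens <- vapply(g3$chromosomes, nchar, integer(1))
  expect_true(all(ann$start >= 0 & ann$end <= lens[ann$chrom] &
                    ann$start < ann$end))
  # elements embedded within the centromere interval
  el <- ann[ann$role %in% c("ATHILA5", "ATHILA_other"), ]
  cen <- g3$centromeres
  expect_true(all(el$start >= cen$start[match(el$chrom, cen$chrom)] &
                    el$end <= cen$end[match(el$chrom, cen$chrom)]))
  # element longer than the centromere is a configuration error
  expect_error(build_toy_genome(simulation_config(seed = 1),
                                element_length = 30000L),
               "centromere")
})

test_that("simulated calls respect count conservation and genome sequence", {
  calls <- simulate_methylome(tiny_genome, genotype_preset("wildtype"),
                              tiny_cfg, tiny_template)
  expect_true(all(calls$n_meth <= calls$n_total))
  expect_true(all(calls$n_total >= 1))
  # every emitted position is a genomic C (+) or G (-)
  for (chrom in unique(calls$chrom)) {
    s <- strsplit(tiny_genome$chromosomes[[chrom]], "")[[1]]
    cc <- calls[calls$chrom == chrom, ]
    expect_true(all(s[cc$pos[cc$strand == "+"] + 1] == "C"))
    expect_true(all(s[cc$pos[cc$strand == "-"] + 1] == "G"))
  }
  # degenerate parameter: all-zero targets give all-zero methylated counts
  zero <- genotype_spec("zero", matrix(0, 5, 3,
    dimnames = list(c("satellite_array", "ATHILA5", "ATHILA_other", "gene",
                      "background"), c("CG", "CHG", "CHH"))))
  cz <- simulate_methylome(tiny_genome, zero, tiny_cfg, tiny_template)
  expect_true(all(cz$n_meth == 0))
  # unknown role is reported by name
  tpl_bad <- tiny_template
  tpl_bad$role[1] <- "mystery_feature"
  expect_error(simulate_methylome(tiny_genome, zero, tiny_cfg, tpl_bad),
               "mystery_feature")
})

test_that("hypomethylated state loses CG but retains CHH at satellites", {
  calls <- simulate_methylome(std_genome, genotype_preset("hypomethylated"),
                              std_cfg, std_template)
  cen <- std_genome$centromeres
  sat <- calls[calls$chrom == "Chr5" &
                 calls$pos >= cen$start[cen$chrom == "Chr5"] &
                 calls$pos < cen$end[cen$chrom == "Chr5"], ]
  lev <- function(ctx) {
    d <- sat[sat$context == ctx, ]
    sum(d$n_meth) / sum(d$n_total)
  }
  expect_lt(lev("CG"), lev("CHH"))
  expect_lt(lev("CG"), 0.1)
})

test_that("hairpin restoration raises CHG in homologous spans by the configured effect", {
  hp <- genotype_preset("hairpin_rescued")
  base <- genotype_preset("hypomethylated")
  calls_hp <- simulate_methylome(std_genome, hp, std_cfg, std_template)
  calls_b <- simulate_methylome(std_genome, base, std_cfg, std_template)
  hom <- std_template$hp_homolog & std_template$context == "CHG"
  key <- function(calls) paste(calls$chrom, calls$pos, calls$strand)
  tkey <- paste(std_template$chrom, std_template$pos, std_template$strand)
  lev_hom <- function(calls) {
    sel <- key(calls) %in% tkey[hom] & calls$context == "CHG"
    sum(calls$n_meth[sel]) / sum(calls$n_total[sel])
  }
  observed_effect <- lev_hom(calls_hp) - lev_hom(calls_b)
  configured <- hp$hairpin_levels[["CHG"]] -
    base$levels["ATHILA5", "CHG"]
  expect_lt(abs(observed_effect - configured), 0.03)
  # CG untouched by the hairpin
  lev_cg <- function(calls) {
    homcg <- std_template$hp_homolog & std_template$context == "CG"
    sel <- key(calls) %in% tkey[homcg] & calls$context == "CG"
    sum(calls$n_meth[sel]) / sum(calls$n_total[sel])
  }
  expect_lt(abs(lev_cg(calls_hp) - lev_cg(calls_b)), 0.03)
})

test_that("empirical methylation means converge to configured targets at high coverage", {
  cfg <- simulation_config(seed = 33, coverage_mean = 200,
    chrom_lengths = tiny_cfg$chrom_lengths, focal_chrom = "Chr5")
  wt <- genotype_preset("wildtype")
  calls <- simulate_methylome(tiny_genome, wt, cfg, tiny_template)
  key <- paste(calls$chrom, calls$pos, calls$strand)
  tkey <- paste(tiny_template$chrom, tiny_template$pos,
                tiny_template$strand)
  role <- tiny_template$role[match(key, tkey)]
  for (r in c("satellite_array", "gene", "background")) {
    for (ctx in c("CG", "CHG", "CHH")) {
      sel <- role == r & calls$context == ctx
      emp <- sum(calls$n_meth[sel]) / sum(calls$n_total[sel])
      expect_lt(abs(emp - wt$levels[r, ctx]), 0.02)
    }
  }
})

test_that("recombinant lines follow the crossing scheme", {
  # no-recombination limit: whole-chromosome blocks; sterile lines carry the
  # entire focal chromosome from the hypomethylated parent
  cfg0 <- simulation_config(seed = 5, crossover_rate_arm = 1e-9,
                            crossover_rate_centromere = 1e-10,
                            n_recombinant_lines = 30)
  mos0 <- simulate_recombinant_lines(std_genome, cfg0)
  for (m in mos0) {
    expect_identical(nrow(m$blocks), 5L)
    foc <- m$blocks[m$blocks$chrom == "Chr5", ]
    expect_identical(m$phenotype,
                     if (foc$origin == "ddm1_derived") "sterile"
                     else "fertile")
  }
  # transmission probability: with free segregation and no crossovers the
  # causative interval is inherited hypomethylated with probability 1/2
  # (gamete enumeration: 2 equiprobable whole-chromosome gametes)
  n_lines <- 400
  cfg1 <- simulation_config(seed = 6, crossover_rate_arm = 1e-9,
                            crossover_rate_centromere = 1e-10,
                            n_recombinant_lines = n_lines)
  mos1 <- simulate_recombinant_lines(std_genome, cfg1)
  frac <- mean(vapply(mos1, `[[`, "", "phenotype") == "sterile")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_lines))
  # a line whose causative interval is WT-derived is fertile
  causative <- data.frame(chrom = "Chr5", start = 20000, end = 22000)
  mos2 <- simulate_recombinant_lines(std_genome, cfg0, causative)
  wt_lines <- Filter(function(m)
    interval_origin(m$blocks, causative) == "WT_derived", mos2)
  expect_true(all(vapply(wt_lines, `[[`, "", "phenotype") == "fertile"))
  cfg_zero <- simulation_config()
  cfg_zero$n_recombinant_lines <- 0L
  expect_error(simulate_recombinant_lines(std_genome, cfg_zero),
               "at least one")
})

test_that("crossover counts match the configured Poisson rates", {
  cfg <- simulation_config(seed = 11, crossover_rate_arm = 1.2,
                           crossover_rate_centromere = 0.1,
                           n_recombinant_lines = 250)
  mos <- simulate_recombinant_lines(std_genome, cfg)
  # breakpoints per chromosome = blocks - 1; split into centromere vs arm by
  # position
  cen <- std_genome$centromeres
  n_arm <- 0; n_cen <- 0
  for (m in mos) {
    for (chrom in unique(m$blocks$chrom)) {
      b <- m$blocks[m$blocks$chrom == chrom, ]
      bps <- b$start[-1]
      cs <- cen$start[cen$chrom == chrom]; ce <- cen$end[cen$chrom == chrom]
      n_cen <- n_cen + sum(bps >= cs & bps < ce)
      n_arm <- n_arm + sum(bps < cs | bps >= ce)
    }
  }
  n_meioses <- length(mos) * 5
  # expected arm crossovers: two arms at rate 1.2 each
  expect_lt(abs(n_arm / n_meioses - 2 * 1.2),
            4 * sqrt(2 * 1.2 / n_meioses))
  expect_lt(abs(n_cen / n_meioses - 0.1), 4 * sqrt(0.1 / n_meioses))
})

test_that("chip coverage simulation recovers configured enrichment contrasts", {
  expect_error(simulate_chip_coverage(std_genome,
    c(satellite_array = -1, ATHILA5 = 1, ATHILA_other = 1, gene = 1,
      background = 1), std_cfg), ">= 0")
  # null multiplier: log2 ratio metaplot flat at 0
  null_tracks <- simulate_chip_coverage(std_genome,
    c(satellite_array = 1, ATHILA5 = 1, ATHILA_other = 1, gene = 1,
      background = 1), std_cfg)
  enr <- chip_enrichment(null_tracks$ip, null_tracks$input)
  grp <- athila_groups(std_genome)
  prof <- metaprofile(enr, grp$ATHILA_other, std_lens)
  expect_lt(abs(body_mean(prof)), 0.1)
  # hairpin-restored state: ATHILA5 group exceeds other ATHILA
  hp_tracks <- simulate_chip_coverage(std_genome,
    chip_multipliers("hairpin_rescued"), std_cfg)
  enr_hp <- chip_enrichment(hp_tracks$ip, hp_tracks$input)
  expect_gt(body_mean(metaprofile(enr_hp, grp$ATHILA5, std_lens)),
            body_mean(metaprofile(enr_hp, grp$ATHILA_other, std_lens)) + 0.5)
})

test_that("cytology simulation matches its configured rates", {
  cfg <- simulation_config(seed = 21)
  rec0 <- simulate_cytology(cfg, rates = c(WT = 0))
  expect_identical(missegregation_rate(rec0, "WT")$rate, 0)
  expect_identical(missegregation_rate(rec0, "WT")$n, cfg$n_cells_scored)
  # all events attributed to the focal chromosome at bias 1
  rec1 <- simulate_cytology(cfg, rates = c(mut = 0.4), chr5_bias = 1)
  ev <- rec1$event_chromosome[!is.na(rec1$event_chromosome)]
  expect_true(all(ev == "Chr5"))
  expect_error(simulate_cytology(cfg, rates = c(m = 0.3), chr5_bias = 1.2),
               "chr5_bias")
  # mean estimated rate over replicates approaches the configured rate
  est <- vapply(1:40, function(r)
    missegregation_rate(simulate_cytology(cfg, rates = c(m = 0.31),
                                          seed = 1000 + r), "m")$rate,
    numeric(1))
  expect_lt(abs(mean(est) - 0.31), 3 * sqrt(0.31 * 0.69 / (40 * 100)))
})

test_that("identical configs give byte-identical simulated outputs", {
  c1 <- simulate_methylome(tiny_genome, genotype_preset("wildtype"),
                           tiny_cfg, tiny_template)
  c2 <- simulate_methylome(tiny_genome, genotype_preset("wildtype"),
                           tiny_cfg, tiny_template)
  expect_identical(c1, c2)
  r1 <- simulate_cytology(tiny_cfg)
  r2 <- simulate_cytology(tiny_cfg)
  expect_identical(r1, r2)
  m1 <- simulate_recombinant_lines(tiny_genome, tiny_cfg)
  m2 <- simulate_recombinant_lines(tiny_genome, tiny_cfg)
  expect_identical(m1, m2)
})
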