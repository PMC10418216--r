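target_levels_for <- function(template, genotype) {
  # memoize per template: panels simulate many methylomes from the same
  # genotype spec and the target-level vector is deterministic
  lv <- genotype$levels
  ri <- match(template$role, rownames(lv))
  if (anyNA(ri))
    stop("unknown annotation role: ",
         paste(unique(template$role[is.na(ri)]), collapse = ", "))
  cache <- attr(template, "level_cache")
  ck <- paste(genotype$name, paste(genotype$levels, collapse = ","),
              genotype$hairpin_restore,
              paste(unlist(genotype$hyper_loci), collapse = ","), sep = "|")
  if (!is.null(cache) && !is.null(cache[[ck]])) return(cache[[ck]])
  level <- lv[cbind(ri, match(template$context, colnames(lv)))]
  if (genotype$hairpin_restore) {
    for (ctx in c("CHG", "CHH")) {
      idx <- template$hp_homolog & template$context == ctx
      level[idx] <- pmax(level[idx], genotype$hairpin_levels[[ctx]])
    }
  }
  if (!is.null(genotype$hyper_loci)) {
    hl <- genotype$hyper_loci
    for (k in seq_len(nrow(hl))) {
      hit <- template$chrom == hl$chrom[k] &
        template$pos >= hl$start[k] & template$pos < hl$end[k]
      level[hit] <- pmax(level[hit],
                         genotype$hyper_levels[template$context[hit]])
    }
  }
  if (!is.null(cache)) cache[[ck]] <- level
  level
}

#' Simulate a per-cytosine methylation call table
#'
#' Emulates WGBS/long-read methylation calls for one genotype on the toy
#' genome: per cytosine (both strands), total read count is Poisson with mean
#' `config$coverage_mean` and the methylated count is Binomial(total, level),
#' where the level is the genotype's target for that (annotation role,
#' context), modified by hairpin restoration and hypermethylated loci.
#' Cytosines drawing zero coverage are not emitted.
#'
#' @param genome a `toy_genome`.
#' @param genotype a [genotype_spec()].
#' @param config a [simulation_config()].
#' @param template optional precomputed [methylome_template()] (computing it
#'   once speeds up panels of many methylomes).
#' @param seed optional seed override; defaults to a stream derived from
#'   `config$seed` and the genotype name.
#' @return calls data.frame: chrom, pos (0-based), strand, context, n_meth,
#'   n_total (all `n_total >= 1`, `n_meth <= n_total`).
#' @examples
#' cfg <- simulation_config(seed = 1)
#' g <- build_toy_genome(cfg)
#' calls <- simulate_methylome(g, genotype_preset("wildtype"), cfg)
#' head(calls)
#' @export
simulate_methylome <- function(genome, genotype, config,
                               template = NULL, seed = NULL) {
  stopifnot(inherits(genome, "toy_genome"),
            inherits(genotype, "genotype_spec"))
  template <- template %||% methylome_template(genome)
  level <- target_levels_for(template, genotype)
  seed <- seed %||% derive_seed(config$seed,
                                paste0("methylome:", genotype$name))
  with_seed(seed, {
    n_total <- stats::rpois(nrow(template), config$coverage_mean)
    keep <- n_total > 0L
    n_meth <- integer(sum(keep))
    n_meth <- stats::rbinom(sum(keep), n_total[keep], level[keep])
    fast_df(chrom = template$chrom[keep],
            pos = template$pos[keep],
            strand = template$strand[keep],
            context = template$context[keep],
            n_meth = n_meth,
            n_total = n_total[keep])
  })
}
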