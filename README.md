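# epicen

Mapping a heritable centromeric epiallele — and quantifying its cellular
consequences — from per-cytosine methylation data.

When Arabidopsis loses both the chromatin remodeler DDM1 and its
RNA-dependent RNA polymerases, pericentromeric heterochromatin is
heritably hypomethylated, plants become sterile, and chromosome 5
mis-segregates at mitosis. Locating the responsible epiallele and showing
that small RNAs against a single centromeric retrotransposon family
(ATHILA5) rescue it requires a chain of computational procedures that
`epicen` packages for reuse:

* **Methylation IO** — strand-aware CG/CHG/CHH context classification,
  a ≥3-read coverage filter, signed [−1, 1] browser tracks (minus-strand
  ratios negated), and TSV call tables in Bismark-CX-like and
  bedMethyl-like dialects.
* **DMR calling** — count-weighted methylation on a fixed 300 bp grid,
  where `total_level = level_CG + level_CHG + level_CHH`, and the
  suppressor rule: a window is a hypermethylated DMR when the quadruple
  mutant retains < 40% of the triple mutant's methylation *and* the
  suppressor recovers > 60% of it; calls are intersected across
  suppressor lines (Venn counts, adjacent windows merged).
* **Epigenetic mapping** — phenotype-pooled window profiles and a linked
  region scan on the fertile − sterile methylation difference; McrBC-style
  marker epigenotyping; dominant-epiallele interval logic
  (∩ sterile spans ∖ ∪ fertile spans); a bulked-segregant SNP scan for
  recessive suppressors (pool allele frequencies 1 vs 1/3, Δ = 2/3 at the
  causal site); CAPS restriction-site gain/loss checks.
* **Metaplots** — element-anchored profiles (scaled body + fixed flanks,
  equal weight per element, strand-oriented) for methylation per context
  and for log2(IP/input) ChIP enrichment.
* **Cytology statistics** — mis-segregation rates with Clopper–Pearson
  CIs, Fisher exact contrasts, per-chromosome FISH attribution, cohesion
  dot classes, chromocenter and immunofluorescence ratios, and
  silique-length fertility classes.
* **Synthetic data** — a five-chromosome toy genome (satellite arrays
  with embedded ATHILA/ATHILA5 elements, genes, a hairpin source element)
  and generators for methylomes (Poisson coverage, Binomial methylation),
  recombinant epigenotype mosaics, ChIP tracks, SNP pools and cytology
  tables, so the full pipeline runs and is tested without external data.

See `vignettes/epicen-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

```r
library(epicen)

cfg <- simulation_config(seed = 101)
genome <- build_toy_genome(cfg)
tpl <- methylome_template(genome)

## a 4-suppressor panel with one planted shared hypermethylated locus
panel <- simulate_suppressor_panel(genome, cfg, template = tpl)
res <- panel_shared_dmrs(panel, width = 300)
res$merged
#>   chrom start   end n_windows
#> 1  Chr5 17100 18300         4
res$venn
#>                                               pattern  n
#>                                          suppressor_1 14
#>  suppressor_1&suppressor_2&suppressor_3&suppressor_4   4
#>                                          suppressor_2 15
#>                                          suppressor_3 14
#>                                          suppressor_4 15
```

The 300 bp / <40% retention / >60% recovery rule finds 18–19 passing
windows per suppressor; intersecting the four lines leaves exactly one
merged region of four adjacent windows (Chr5:17100–18300), which overlaps
the planted common locus (Chr5:17000–18200) — each line's five private
hypermethylated loci (14–15 windows each) drop out of the intersection.

```r
rec <- simulate_cytology(cfg)
missegregation_rate(rec, "rdr1;2;6 ddm1")
#> $rate   0.3
#> $n      100
#> $ci     0.212 0.400   (Clopper–Pearson 95%)
fertility_class(8)$seeds_band
#> "10-15 seeds / silique"
```

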