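---
title: "Methods: mapping a centromeric epiallele and scoring its consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a centromeric epiallele and scoring its consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicen)
```

## The problem

In Arabidopsis, loss of the chromatin remodeler DDM1 heritably
hypomethylates pericentromeric heterochromatin. In combination with loss of
the RNA-dependent RNA polymerases (RDR1/2/6), plants become sterile and
mis-segregate chromosome 5 at mitosis; fertility co-segregates
epigenetically with the hypomethylated centromeric region of chromosome 5,
where a family of ATHILA5 retrotransposons is embedded in the satellite
array. An RNAi hairpin against one centromeric ATHILA5 restores non-CG
methylation, H3K9me2 and accurate segregation. `epicen` implements the
computational side of that study design as a reusable pipeline:

1. per-cytosine methylation processing (context classification, coverage
   filtering, signed browser tracks);
2. fixed-grid windowed methylation and a retention/recovery rule for
   suppressor-hypermethylated DMRs, intersected across suppressor lines;
3. methylation-based bulked-segregant mapping of epigenetic recombinant
   lines, McrBC-style marker epigenotyping and interval logic, and an
   EMS suppressor SNP scan with CAPS marker checks;
4. transposon-anchored metaplots of methylation and ChIP enrichment;
5. statistics for scored cytology (mis-segregation rates, FISH
   attribution, cohesion dot classes, chromocenter and IF ratios,
   fertility classes).

Because the underlying sequencing data are not recomputable at desk scale,
a synthetic-data module generates a toy genome and all downstream inputs
with the statistical structure the analyses assume. Every analysis stage is
validated against planted truth and independent oracles on that simulator.

## The toy genome and what it emulates

`build_toy_genome()` produces five 50 kb chromosomes (defaults in
`simulation_config()`). Each carries a central satellite array (tandem
180 bp units spanning 30--70% of the chromosome) with retrotransposon
elements embedded in it and genes on the arms. The focal chromosome
("Chr5") carries three ATHILA5-like elements interspersed with other
ATHILA; the last ATHILA5 copy is the hairpin source ("CEN5-ATHILA5"), and
the hairpin span covers its central 70%. Five chromosomes are kept — rather
than one — so that per-chromosome attribution of mis-segregation events
remains a meaningful analysis.

What the toy genome does *not* emulate: realistic satellite higher-order
structure and sequence identity gradients, element degeneracy and
truncation, realistic gene density, and the true 100× larger scale.
Passing planted-truth tests therefore demonstrates the correctness of the
*procedures* (windowing, thresholding, intersection, interval logic), not
their power on real repeat-rich genomes, where mappability and coverage
biases — deliberately absent from the simulator — dominate.

## Methylation model

Each genotype is a matrix of target methylation levels per annotation role
and context (CG/CHG/CHH), with all values in [0,1]
(`genotype_spec()`, presets in `genotype_preset()`):

* the methylated ("wildtype", also the RdRP triple mutant) state has
  heavily CG/CHG-methylated heterochromatin with low CHH;
* the hypomethylated (remodeler-mutant) state loses CG and CHG at
  satellites but retains CHH there, and additionally loses CHH at
  elements (the RdRP-dependent component);
* suppressor states add ectopic hypermethylation in all three contexts at
  configured loci;
* the hairpin-rescued state raises CHG and CHH — never CG — within the
  hairpin-homologous sub-span of every ATHILA5 copy. The homologous span is
  mapped proportionally from the source element to each copy, reflecting
  homology-directed (RNA-guided) restoration; restricting restoration to
  the source element alone would contradict the family-wide contrast the
  metaplots are designed to detect.

Counts are simulated per cytosine on both strands: total reads Poisson
with mean `coverage_mean` (default 20), methylated reads Binomial at the
target level. These are the simplest models with the correct support; no
overdispersion, bisulfite conversion error, or mapping bias is modeled.
Convergence of empirical means to targets is tested at coverage 200 with
tolerance 0.02.

One root seed drives everything; each operation derives its own stream
(`derive_seed()`) so that modules are independently reproducible and
re-running one stage does not perturb another.

## Windowing and the DMR rule

`window_methylation()` summarises calls on a fixed grid; the per-context
level is count-weighted (`sum(n_meth)/sum(n_total)`), and `total_level`
is the *sum of the three context levels* (range [0,3]). The alternative —
pooling counts across contexts — is available simply by windowing
unsplit calls; summing levels is the default because the three contexts
have very different cytosine densities and the rule is stated on summed
levels. A context with no covered cytosines contributes 0 to
`total_level` when at least one context is defined; fully uncovered
windows are skipped rather than fabricated.

`call_suppressor_dmrs()` classifies 300 bp windows by two ratios against
the methylated (triple-mutant) baseline: retention
(quadruple/triple) and recovery (suppressor/triple). A window passes when
retention < 0.4 and recovery > 0.6, both strict, with no epsilon — the
thresholds are quoted inequalities, not fitted parameters. The recovery
baseline is the unsilenced parent; a rescaled mode
`(suppressor − quadruple)/(triple − quadruple)` is exposed as an option
because "recovering more than 60%" is ambiguous between the two readings.
`intersect_dmrs()` takes windows passing in *all* suppressor lines,
reports Venn counts over all membership patterns, and merges adjacent
shared 300 bp windows into maximal runs — which is how a 300 bp calling
grid yields kb-scale shared DMRs.

## Mapping

Pooled mapping (`pool_profiles()` + `linked_region_scan()`) averages
per-line window profiles within phenotype groups with equal weight per
line, then ranks maximal runs of windows where the fertile pool exceeds
the sterile pool by `delta_min` (default 0.2 on `total_level`), scoring
runs by length × mean excess. The mapping-window default is 100 kb to
match genome-scale practice; on the 50 kb toy chromosomes, analyses use a
5 kb grid — a scale choice, since one 100 kb window per toy chromosome
carries no positional information.

Marker epigenotyping (`epigenotype_markers()`) models McrBC/PCR scoring
as a thresholded local methylation call (CG evidence by default, window
2 kb; `ddm1_derived` below 0.2, `WT_derived` above 0.5). The thresholds
are conventions for a gel-based presence/absence assay and are
configurable. `map_interval()` assumes a dominant epiallele: the interval
is the intersection of sterile lines' hypomethylated spans minus the
union of fertile lines' spans. Because markers only bracket recombination
breakpoints, sterile spans are taken *expansively* (to the nearest
discordant marker) and fertile spans *conservatively* (the marker run
itself); this asymmetry guarantees the true locus is never excluded by
breakpoint uncertainty, at the cost of a slightly wider interval — the
appropriate trade-off for a mapping interval. An empty result yields an
inconsistency report naming lines whose removal restores consistency.

The suppressor SNP scan (`bsa_snp_scan()`) uses the recessive segregant
design: selfed progeny of a heterozygous parent give mutant allele
frequency 1 in the suppressor pool and 1/3 among phenotypically normal
sibs, so the per-SNP frequency difference peaks at 2/3. The windowed mean
difference is reported with the peak region (contiguous windows above
half the peak). `caps_check()` classifies a SNP as creating or destroying
a restriction site by counting motif occurrences (either strand)
overlapping the SNP in the reference versus alternate sequence.

## Metaplots and ChIP enrichment

`metaprofile()` rescales each element body to 40 bins with 10 fixed-width
flank bins per side (500 bp flanks by default; bin counts are recorded in
the profile's attributes since they are layout conventions, not
measurements). Elements are averaged with equal weight — the standard
metaplot convention, so long elements do not dominate — and minus-strand
elements are reversed. Methylation profiles are computed per context with
count-weighted bin means; elements shorter than the bin count contribute
through fractional-overlap interpolation and are flagged.

`chip_enrichment()` computes `log2((ip+p)/(input+p))`. Two normalization
modes exist because they answer different questions: `"depth"` (default)
scales both tracks to a common total, making the result invariant to
sequencing depth — but it also scales out genuine genome-wide enrichment,
so a uniform 4× IP excess reads as 0; `"none"` preserves raw ratios, so
the same uniform excess reads as 2.0 log2 units. Tests pin both
behaviours.

## Cytology statistics

A cell mis-segregates when it shows ≥1 lagging chromosome (multi-event
cells count once). Rates come with Clopper–Pearson exact 95% intervals
(`stats::binom.test`); contrasts between genotypes use Fisher's exact
test, validated against direct hypergeometric enumeration on all small
tables. FISH attribution is the per-probe colocalized fraction of
abnormal cells — probes are separate experiments, so proportions need not
sum to 1. Cohesion is summarised as the dot-count histogram with reduced
fraction (3 or 4 dots)/n; 1-dot nuclei are reported separately as
unclassified. Chromocenter condensation is the fraction of nuclear signal
in chromocenters, with an error if segmentation reports more chromocenter
than nuclear signal. Fertility classes follow the printed silique-length
bins, taken half-open `[3,5), [5,7), [7,9), [9,11), [11,∞)` mm on the
plant's median length (the printed bins share endpoints, so a convention
is required; lengths below 3 mm fall in the sterile class, and 1–10
seeds per plant is sterile regardless of silique length).

The cytology simulator draws per-cell events at configured genotype rates
(defaults: 0 for methylated genotypes, 0.31 for the quadruple mutant,
0.03 under the hairpin), attributes events to the focal chromosome with
probability 0.84, and emits the scoring sizes used throughout: 100
anaphase cells and 30 chromocenters per genotype, 50 cohesion nuclei, 100
phospho-mark dots.

## Problem sizes and numerical choices

Replicated analyses in the test-suite and acceptance script use: one
4-suppressor DMR panel (coverage 20), 100 (tests) / 40 (script)
recombinant panels of 20 lines, 100/40 hairpin metaplot replicates, 40
BSA replicates, and 500/200 calibration replicates at n = 100 cells —
sizes chosen to give binomial standard errors well below the tested
margins while keeping a full run in minutes on one core. Ratios are
compared with strict/non-strict operators exactly as specified, with no
floating-point epsilon; ties in window ranking are resolved by order of
appearance. Panels in which every line shares one phenotype are
uninformative for mapping and are excluded from recovery denominators
(they occur when no line, or every line, inherits the causative
interval).

## Known limitations

* The simulator's per-(role, context) levels are piecewise-constant;
  real methylomes have gradients and element-age structure.
* The recombination model places crossovers uniformly within arm and
  centromere region classes; only the arm/centromere rate contrast is
  biologically anchored.
* Transmission ratios of the recombinant panels are scheme-derived
  (probability 1/2 per chromosome under free segregation), not calibrated
  to observed segregation data, which the source design does not report.
* Strand-merged CG reporting (as some pileup tools produce) is not
  emulated; strands are kept separate throughout, and the CG
  strand-symmetry of the classifier is tested instead.
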