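Package: epicen
Title: Mapping and Quantifying a Heritable Centromeric Epiallele from
    Cytosine Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating a heritable centromeric epiallele and
    quantifying its cellular consequences from per-cytosine methylation
    calls. Implements strand-aware CG/CHG/CHH context classification,
    coverage filtering and signed browser tracks, fixed-grid windowed
    methylation summaries, a retention/recovery rule for calling
    suppressor-hypermethylated differentially methylated regions with
    multi-line intersection, methylation-based bulked-segregant mapping of
    epigenetic recombinant lines, marker epigenotyping and interval logic,
    an EMS bulked-segregant SNP scan with CAPS marker checks,
    transposon-anchored metaplots of methylation and ChIP enrichment, and
    statistics for scored cytology (mis-segregation rates, chromosome
    attribution, cohesion dot classes, chromocenter and immunofluorescence
    ratios, fertility classes). A synthetic-data module generates a toy
    genome and every downstream input with the statistical structure the
    analyses assume, so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
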