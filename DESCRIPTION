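Package: tescreen
Title: Strain-Comparative Screening, Annotation, and Dating of Active
    Transposable Elements from Short Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting transposable-element (TE)
    families that are differentially amplified between two strains of the
    same species, as in hybrid dysgenesis systems. Simulates TE family
    histories (a recently amplified, near-identical clade on a background
    of degraded ancient fragments), genomes and short reads; trims and
    filters reads by quality; assigns reads to a repeat-consensus library
    with a k-mer seed-and-extend aligner; computes reads-per-million
    enrichment ratios with chi-squared tests; profiles per-site coverage
    and major-variant frequency to separate homogeneous (recently active)
    from heterogeneous (degraded) copy populations; annotates candidate
    elements (terminal inverted repeats, open reading frames with alternate
    starts, protein identity); dates genomic fragments via neighbor-joining
    on Jukes-Cantor distances and a molecular clock; and fits the
    sequential ANOVA used for reciprocal-cross RPM expression comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
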