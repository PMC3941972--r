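# tescreen

Strain-comparative screening, annotation, and dating of active transposable
elements (TEs) from short reads.

## What it is for

In hybrid dysgenesis systems, an *inducer* strain carries a recently
amplified, near-identical TE family whose copies escape silencing in
crosses, while the *non-inducer* strain carries only old, degraded
fragments of the same element. `tescreen` implements the computational core
of detecting and characterizing such elements from whole-genome short reads
of the two strains, for geneticists and genome biologists who want each
stage as an explicit, testable R function rather than a chain of opaque
external tools.

The pipeline:

* **Abundance screen** — reads from each strain are assigned to a
  repeat-consensus library by a k-mer seed-and-extend aligner; per-family
  counts are normalized to reads per million mapped,
  *n<sub>c,s</sub>* = 10⁶ · *r<sub>c,s</sub>* / *M<sub>s</sub>*, and compared
  as a fold ratio *R<sub>c</sub>* = *n<sub>c,1</sub>* / *n<sub>c,2</sub>*
  with a Pearson chi-squared test (1 df) on
  [[*r₁*, *M₁*−*r₁*], [*r₂*, *M₂*−*r₂*]].
* **Heterogeneity profile** — per consensus position, the major-variant
  frequency *h<sub>i</sub>* = max base count / total base count among
  aligned read bases. *h* ≈ 1 along the element marks a homogeneous,
  recently active copy population; scattered lower *h* marks degraded
  lineages.
* **Annotation** — genomic copies extracted with flanks, reduced to a
  shared core consensus, then terminal inverted repeats (TIRs), six-frame
  ORFs with alternate in-frame starts, and global protein identity
  (BLOSUM62).
* **Fragment dating** — all genomic fragments anchored to the consensus,
  Jukes–Cantor distances *d* = −(3/4)·ln(1 − 4*p*/3), neighbor-joining
  tree, and each terminal branch length *L* (substitutions/bp) converted to
  an age *t* = *L*/(μ·*g*) (defaults μ = 1.45×10⁻⁹ subs/bp/generation,
  *g* = 10 generations/year, so *L* = 0.10 dates to ≈ 7 My).
* **Expression ANOVA** — sequential (Type I) fixed-effect ANOVA of
  per-library RPM expression over treatment (dysgenic vs non-dysgenic), age
  class, barcode, and treatment×age, with broom-style `tidy()`/`glance()`.
* **Synthetic data** — a first-class generator for TE family histories
  (active clade + degraded fragments), strain genomes with truth tables,
  error-bearing FASTQ-style reads, and the 16-library factorial expression
  design, so the whole pipeline is testable without external data.

## Worked example

Simulate an inducer/non-inducer strain pair carrying a 1708-bp element with
235-bp TIRs (20 active copies at 1% divergence in the inducer; 8 shared
degraded fragments at 12–20% divergence), sequence both at 8×, and run the
screen:

```r
library(tescreen)

hot <- te_family_spec("fam_hot", consensus_length = 1708, tir_length = 235,
                      n_active_copies = c(inducer = 20, noninducer = 0),
                      active_divergence = 0.01, n_degraded_copies = 8,
                      degraded_divergence_range = c(0.12, 0.20), seed = 701)
gs <- build_genomes(hot, background_length = 2e5, seed = 703)
reads_i <- simulate_reads(gs, mean_coverage = 8, strain = "inducer",    seed = 704)
reads_n <- simulate_reads(gs, mean_coverage = 8, strain = "noninducer", seed = 705)

scr <- run_screen(reads_i, reads_n, gs$library,
                  strain_labels = c("inducer", "noninducer"))
scr$enrichment[, c("family_id", "rpm_a", "rpm_b", "fold", "statistic", "p_value")]
#> # A tibble: 1 × 6
#>   family_id   rpm_a  rpm_b  fold statistic p_value
#>   <chr>       <dbl>  <dbl> <dbl>     <dbl>   <dbl>
#> 1 fam_hot   154689. 11921.  13.0     2230.       0
scr$activity
#> # A tibble: 2 × 6
#>   strain     family_id n_defined mean_h median_coverage classification
#>   <chr>      <chr>         <int>  <dbl>           <dbl> <chr>
#> 1 inducer    fam_hot        1708  0.983           9023. active-like
#> 2 noninducer fam_hot        1288  0.919            547. degraded-like
```

The family is 13-fold enriched in the inducer strain (chi-squared p ≈ 0)
and its read population is homogeneous (mean *h* = 0.983, active-like) in
the inducer but heterogeneous (0.919, degraded-like) in the non-inducer —
the joint signature the screen calls a candidate
(`scr$candidates$family_id` is `"fam_hot"`).

Characterizing the candidate in the inducer genome recovers the element's
structure and its two-epoch history:

```r
ch <- run_characterize(gs$genomes[["inducer"]], gs$library$consensus,
                       tir_min_len = 50)
ch
#> TE characterization
#>   copies extracted:  3
#>   core length:       1708 bp
#>   TIR length:        235 bp (identity 1)
#>   fragments dated:   27
summary(ch$ages$ages$branch_length)
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> 0.002793 0.007698 0.009992 0.046764 0.062540 0.201985
```

The planted 235-bp TIRs and 1708-bp core are recovered exactly, and the
terminal branch lengths are bimodal: the recent burst sits near 0.005–0.01
substitutions/bp (ages of a few hundred thousand years under the default
clock) while the degraded cohort spreads over 0.1–0.2 substitutions/bp —
millions of years (`plot_age_distribution(ch$ages)` draws the histogram).

The same arithmetic applies directly to published run sizes:

```r
coverage_estimate(43.7e6, 100, 2, 364e6)   # 24.01  (~24x)
branch_length_to_age(0.10) / 1e6            # 6.90   (~7 My)
```

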