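---
title: "Screening and dating strain-specific transposable element activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and dating strain-specific transposable element activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tescreen)
library(dplyr)
```

## The problem

In hybrid dysgenesis systems, crosses between an *inducer* strain (whose
paternally inherited transposable elements, TEs, escape maternal silencing)
and a *non-inducer* strain produce sterile or mutation-loaded offspring. A
classic signature of the responsible elements is a recently amplified,
near-identical copy family present in the inducer strain but absent — except
for old, degraded fragments — from the non-inducer strain.

`tescreen` implements the desk-scale computational core of that comparison:

1. **Abundance screen.** Short reads from each strain are assigned to a
   repeat-consensus library; per-family counts are normalized to reads per
   million mapped (RPM) and compared between strains as a fold ratio with a
   Pearson chi-squared test on the 2×2 family-vs-rest × strain table.
2. **Heterogeneity profile.** For a candidate family, the per-position
   *major-variant frequency* $h_i$ — the fraction of aligned read bases
   equal to the most common base at consensus position $i$ — separates a
   homogeneous, recently active copy population ($h_i \approx 1$) from a
   heterogeneous degraded one.
3. **Element annotation.** Near-identical genomic copies are extracted with
   flanks, reduced to a shared core consensus, and annotated with terminal
   inverted repeats (TIRs), open reading frames with alternate in-frame
   starts, and protein identity to known transposases.
4. **Fragment dating.** All genomic fragments of the element are anchored to
   the consensus (the local-alignment-output-as-alignment construction),
   pairwise Jukes–Cantor distances feed a neighbor-joining tree, and each
   terminal branch length $L$ (substitutions/bp) converts to an age
   $t = L / (\mu g)$ with substitution rate $\mu$ per bp per generation and
   $g$ generations per year.
5. **Expression ANOVA.** Per-library RPM expression from a reciprocal-cross
   design is decomposed by a sequential (Type I) fixed-effect ANOVA with
   terms treatment, age, barcode, and treatment×age.

Because the original strain read sets are not publicly retrievable, the
package ships a first-class synthetic-data module that generates the exact
situation the method assumes, with full truth tables, so every stage is
testable end to end.

## The synthetic model

`te_family_spec()` describes a two-epoch family history:

* an **ancestral consensus** of `consensus_length` bp whose first and last
  `tir_length` bp are exact reverse complements (the TIRs of a cut-and-paste
  DNA transposon), optionally carrying a planted ORF so annotation recovery
  has a known truth;
* an **active clade**: per-strain copy numbers mutated from the consensus at
  `active_divergence` (default 1%), modeling the recent amplification;
* **degraded fragments**: shared between strains, each mutated at a rate
  drawn from `degraded_divergence_range` (default 10–20%) and truncated from
  a uniformly chosen end to a fraction in `truncation_fraction_range`.

Mutation is independent per-site substitution to one of the three
alternative bases, with no indels. This choice keeps every downstream
statistic analytically checkable: realized divergence is binomial around its
parameter, the expected major-variant frequency under read error rate $e$ is
$1 - e$, and pairwise distances have the Jukes–Cantor closed form. Indel
processes, rate heterogeneity across sites, nested insertions, and
segregating polymorphism within a strain are *not* modeled; passing tests
therefore demonstrate correctness of the computations, not robustness to
every property of real genomes.

Genomes are built by inserting copies at uniformly drawn points of a shared
random background on random strands (point insertion makes overlap
impossible by construction). Reads are single-end, uniform-start,
random-strand, with per-base substitution errors and constant Phred+33
quality, plus optional low-quality 3′ tails to exercise the quality filters.
Paired-end simulation is deliberately out of scope: the analysis this
package reproduces used only one end of each pair, because pairs are not
independent observations for abundance counting.

The expression generator produces the 16-observation design behind the
ANOVA: 2 treatments × 2 age classes, two index (barcode) libraries per RNA
sample, each sequenced on two lanes. Barcodes are drawn from **three**
labels varying within treatment×age cells, so the barcode term carries 2
degrees of freedom and the residual 10 — the printed structure of the
published tables this package's arithmetic reproduces. The published methods
text ("two index libraries") would naively suggest a 2-level factor; the
printed Df column is treated as authoritative, and the model formula is an
argument, so either structure can be fit.

## Read quality control

The cleaning rule is implemented literally as two composable filters:

* `trim_3prime()` removes the maximal 3′-terminal run of bases below
  `qual_threshold` (default Q20), capped at `max_3prime_trim` bases
  (default 16). Trimming is run-based, not window-based; internal bases are
  never touched, so outputs are always prefixes of inputs.
* `filter_reads()` discards reads with more than `max_low_qual_bases`
  (default 2) remaining low-quality bases, or shorter than
  `min_length_after_trim` (default 25 bp — long enough that a surviving read
  still seeds the 15-mer assigner with several independent seeds).

Whether the original pipeline's "up to 16 bp" trimming was run-based or
window-based is not recoverable; run-based is the simplest reading and is
recorded here as this package's definition, not an inference about the
original tool. Phred+33 is the only supported encoding.

## Read assignment and the enrichment screen

External mappers are a non-goal; the package's assigner is a transparent
seed-and-extend method designed to be oracle-checkable:

* `kmer_index()` indexes every k-mer (default `k = 15`) of every library
  consensus on both strands.
* `assign_reads()` takes non-overlapping read seeds, looks them up, and
  scores each seeded (family, strand, offset) candidate by a **full gapless
  comparison** of the read against the consensus at that offset, clipped at
  consensus ends. Best identity wins; ties break to longer aligned length,
  then lexicographically smallest family id. Reads under `min_identity`
  (default 0.85) or `min_aligned_fraction` (default 0.5) stay unassigned —
  a value, not an error.

Gapless scoring is exact under the package's substitution-only model, and
the test suite verifies agreement with an exhaustive Smith–Waterman oracle
on small instances wherever best and second-best families are separated by
at least one substitution. The identity default of 0.85 is deliberately
permissive so that reads from ~15%-diverged degraded copies still map, which
is what makes the non-inducer heterogeneity profile informative. A SAM
import path (`import_sam()`) lets externally mapped reads enter the same
count table and pileup machinery.

Normalization follows the published construction: $n_{c,s} = 10^6 \, r_{c,s}
/ M_s$ where $M_s$ is the strain's mapped-read denominator. When no
reference genome is available the pipeline substitutes total QC-surviving
reads and records the substitution in the report — an approximation that is
conservative for fold ratios as long as both strains' libraries map at
similar rates. The chi-squared test is Pearson's on
$[[r_1, M_1-r_1], [r_2, M_2-r_2]]$, 1 df, no continuity correction; the
published analysis names the test but not the table, so the family-vs-rest
construction is this package's recorded choice. No multiple-testing
correction is applied across families by default, matching the original
screen; `p.adjust` composes trivially downstream if wanted.

`run_screen()` calls a family a **candidate** when its fold ratio in either
direction is at least `fold_threshold` (default 10), its chi-squared p-value
is below `p_threshold` (default 0.001), and its profile is active-like in
exactly one strain. The symmetric ratio rule is a deliberate generalization
of the one-directional published ratio: a family amplified in either strain
is of interest.

## Per-site profiles

`pileup_profile()` tallies aligned read bases per consensus position
(minus-strand reads contribute reverse-complemented bases; `N` bases are
excluded; base counts always sum to depth). $h_i$ is computed from the
aligned bases themselves, *not* from agreement with the consensus — a fixed
non-consensus variant still gives $h_i = 1$, which is exactly the "frequency
of the most common variant" statistic. Positions with depth below
`min_depth` (default 4, below which a frequency is noise) are masked.
`activity_summary()` calls a strain's profile active-like when its mean
defined $h$ is at least `h_threshold` (default 0.95; error-free reads from a
single lineage give $h = 1$, and 1% clade divergence plus 0.1–1% sequencing
error keeps the mean comfortably above 0.95, while two degraded lineages at
10% divergence already drag it far below).

## Annotation

`find_local_matches()` is the shared local matcher: exact k-mer seeds
(default `k = 12`) chained along diagonals (substitution-only alignments
stay on one diagonal) and extended by an X-drop rule — match +1, mismatch
−3, stop when the running score falls 20 below its maximum, report the
boundary at the maximum. In random flanking sequence the expected score
drift is −2/bp, so extension stops within a few bases and boundary overshoot
is typically 0–2 bp; inside a 20%-diverged copy the drift is +0.2/bp, so
fragments are traversed whole. These two regimes are what make TIR-length
and core-length recovery accurate to a few bp at 1% copy divergence.

`core_consensus()` intersects the pairwise alignment footprints of all
copies on the first copy's coordinates and takes a majority-vote base at
each position (ties to copy 1) — the reciprocal-pairwise-comparison
construction for deriving a core element from flanked genomic copies. The
published iterated-search procedure has no stated stopping rule; one round
of footprint intersection is exact under the no-indel model and is what is
implemented.

`detect_tir()` compares the 5′ terminus against the reverse complement of
the 3′ terminus under the same +1/−3 score, anchored at the ends with up to
`max_offset` (default 10) bp of terminal recess, and returns the
best-scoring arm length with identity at least `min_identity`. A full
non-anchored inverted-repeat search is out of scope. `find_orfs()` scans all
six frames for ATG…stop spans, reporting each maximal ORF plus downstream
in-frame ATGs as alternate starts; `protein_identity()` is a global
BLOSUM62 alignment whose identity is matches over alignment columns.
Published protein-identity percentages for known transposases were produced
by a different aligner and are treated as qualitative anchors only.

## Fragment dating

`collect_fragments()` anchors every genomic hit of the consensus to
consensus coordinates, drops fragments under `min_length` (default 100 bp,
below which distances are too noisy) and — when `exclude_tir` is set —
fragments covering fewer than 20 bp outside the TIR intervals, since
TIR-only hits carry no element-internal phylogenetic signal (and palindromic
TIRs generate spurious minus-strand self-hits).

Distances are p-distances over shared ungapped columns with the
Jukes–Cantor correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; pairs
with $p \ge 0.75$ (saturated) or fewer than 30 shared columns are undefined.
Because oppositely truncated fragments can share no columns, `fragment_ages()`
iteratively drops the fragments with the most undefined pairs until the
matrix is complete, reporting how many were removed. The tree is standard
neighbor-joining (negative branch lengths clamped to zero with the deficit
logged); an externally computed newick tree can be supplied directly to
`terminal_branch_lengths()`. NJ on JC distances replaces the original
likelihood tree search deliberately: the reusable computation here is the
dating arithmetic, which is insensitive to the tree-building method at the
contrast sizes that matter (0.005 vs 0.10+ substitutions/bp).

Ages are $t = L/(\mu g)$ with defaults $\mu = 1.45\times10^{-9}$
substitutions/bp/generation and $g = 10$ generations/year — the Drosophila
clock under which $L = 0.10$ gives $\approx 6.9$ million years. The terminal
branch length is used directly (no factor of two): under this clock a
pendant edge measures the substitutions accumulated by that fragment since
its divergence from its reconstructed ancestor.

## Expression ANOVA

`sequential_anova()` fits the fixed-effect model
`rpm ~ treatment + age_class + barcode + treatment:age_class` with
sequential (Type I) sums of squares via `stats::aov` — the same machinery
the original analysis used — and reports df, SS, MS, F against the residual
mean square, and upper-tail F p-values. Singular (confounded) designs are
rejected with the offending term named. A degenerate all-zero response
yields F = 0, p = 1 rather than 0/0. `anova_from_summary()` rebuilds MS, F
and p from a printed `(term, df, sum_sq)` table, which is how the package
re-derives published F statistics when raw observations are unavailable.
`tidy()`/`glance()` methods expose broom-style tibbles, and
`expression_report()` flags significant terms and emits group means with
technical-replicate standard errors for plotting.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere, the R/Bioconductor
  convention.
* **Determinism**: every random operation takes an explicit seed and is a
  pure function of it (via `withr::with_seed`); pipelines re-run to
  identical reports.
* **Tie-breaks** are total orders (identity, then aligned length, then
  family id; consensus ties to copy 1's base), so results are
  permutation-stable.
* **Degenerate inputs** are values where the domain allows it (unassigned
  reads, absent TIRs, empty fragment sets) and errors where it does not
  (zero denominators, singular designs, incomplete distance matrices).
* **Problem sizes**: the shipped tests and the acceptance script use
  backgrounds of 0.1–1 Mb, 1–2 kb elements, and 4–8× coverage — sizes at
  which every stage's behavior is already asymptotic (hundreds to thousands
  of assigned reads per family) while a full run stays interactive on one
  core.

## Worked example

```{r example, eval = FALSE}
hot <- te_family_spec("fam_hot", consensus_length = 1708, tir_length = 235,
                      n_active_copies = c(inducer = 20, noninducer = 0),
                      active_divergence = 0.01, n_degraded_copies = 8,
                      degraded_divergence_range = c(0.12, 0.20), seed = 701)
gs <- build_genomes(hot, background_length = 2e5, seed = 703)
reads_i <- simulate_reads(gs, mean_coverage = 8, strain = "inducer", seed = 704)
reads_n <- simulate_reads(gs, mean_coverage = 8, strain = "noninducer", seed = 705)

scr <- run_screen(reads_i, reads_n, gs$library,
                  strain_labels = c("inducer", "noninducer"))
scr$candidates

ch <- run_characterize(gs$genomes[["inducer"]],
                       gs$library$consensus, tir_min_len = 50)
ch$annotation$tir
plot_age_distribution(ch$ages)
```

## Known limitations

* The assigner and matcher assume substitution-dominated divergence; real
  degraded copies carry indels that would fragment diagonals and shorten
  recovered fragments. A gapped extension would be the natural upgrade.
* Counts are per-read best-hit; families with long shared segments compete
  for reads and a true multi-mapping model is not attempted (the original
  mapper's effective policy is equally unstated).
* The RPM denominator substitution (QC-surviving reads for genome-mapped
  reads) is flagged but unavoidable without a reference genome.
* NJ/JC dating ignores rate heterogeneity and ancestral-state uncertainty;
  ages are order-of-magnitude statements, as in the analysis it mirrors.
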