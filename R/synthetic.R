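#' Specify a synthetic transposable-element family
#'
#' Describes the two-epoch history that the screen is designed to detect: a
#' recently amplified, near-identical ("active") clade whose copy number can
#' differ between strains, superimposed on a set of old, divergent, truncated
#' ("degraded") fragments shared by both strains. The element carries exact
#' terminal inverted repeats (TIRs) in its ancestral consensus and,
#' optionally, a planted open reading frame so that annotation recovery can
#' be tested against known truth.
#'
#' @param family_id Name of the family (used in libraries and truth tables).
#' @param consensus_length Length of the ancestral consensus in bp.
#' @param tir_length Length of each terminal inverted repeat in bp
#'   (`2 * tir_length < consensus_length`).
#' @param n_active_copies Named integer vector, copies of the recent clade
#'   per strain, e.g. `c(strain160 = 30, strain9 = 0)`.
#' @param active_divergence Per-site substitution rate of active copies from
#'   the consensus (fraction, in `[0, 0.75]`).
#' @param n_degraded_copies Number of ancient fragments shared by strains.
#' @param degraded_divergence_range Length-2 numeric, `[min, max]` per-site
#'   divergence of degraded copies.
#' @param truncation_fraction_range Length-2 numeric, `[min, max]` fraction of
#'   the consensus length retained by a degraded copy (truncated from a
#'   uniformly chosen end).
#' @param orf_codons Optional: plant an open reading frame of this many
#'   codons (amino acids, excluding the stop) just inside the left TIR.
#' @param seed Integer seed; identical spec => identical simulation.
#' @return An object of class `te_family_spec`.
#' @export
te_family_spec <- function(family_id = "TE1",
                           consensus_length = 1708,
                           tir_length = 235,
                           n_active_copies = c(strainA = 10, strainB = 0),
                           active_divergence = 0.01,
                           n_degraded_copies = 10,
                           degraded_divergence_range = c(0.10, 0.20),
                           truncation_fraction_range = c(0.2, 0.9),
                           orf_codons = NULL,
                           seed = 1L) {
  stopifnot(
    consensus_length > 0, tir_length >= 0,
    2 * tir_length < consensus_length,
    length(n_active_copies) >= 1, !is.null(names(n_active_copies)),
    all(n_active_copies >= 0), n_degraded_copies >= 0,
    active_divergence >= 0, active_divergence <= 0.75,
    length(degraded_divergence_range) == 2,
    all(degraded_divergence_range >= 0), all(degraded_divergence_range <= 0.75),
    degraded_divergence_range[1] <= degraded_divergence_range[2],
    length(truncation_fraction_range) == 2,
    all(truncation_fraction_range > 0), all(truncation_fraction_range <= 1),
    truncation_fraction_range[1] <= truncation_fraction_range[2]
  )
  if (!is.null(orf_codons)) {
    stopifnot(orf_codons >= 1,
              tir_length + 3 * orf_codons + 3 + 10 < consensus_length - tir_length)
  }
  structure(
    list(
      family_id = family_id,
      consensus_length = as.integer(consensus_length),
      tir_length = as.integer(tir_length),
      n_active_copies = n_active_copies,
      active_divergence = active_divergence,
      n_degraded_copies = as.integer(n_degraded_copies),
      degraded_divergence_range = degraded_divergence_range,
      truncation_fraction_range = truncation_fraction_range,
      orf_codons = if (is.null(orf_codons)) NULL else as.integer(orf_codons),
      seed = as.integer(seed)
    ),
    class = "te_family_spec"
  )
}

# codons that do not stop translation (used for planted ORFs)
non_stop_codons <- function() {
  cods <- names(Biostrings::GENETIC_CODE)
  cods[Biostrings::GENETIC_CODE != "*"]
}

#' Simulate the copies of a TE family
#'
#' Generates a random ancestral consensus with exact terminal inverted
#' repeats, then derives active copies (per strain, low divergence) and
#' degraded copies (shared, high divergence, truncated from one end) by
#' independent per-site substitution.
#'
#' @param spec A [te_family_spec()].
#' @return A list of class `te_family_sim` with elements `consensus`
#'   (character), `copies` (tibble: `copy_id`, `class`, `strain`,
#'   `divergence`, `c_start`, `c_end`, `length`, `sequence`), and `spec`.
#'   `c_start`/`c_end` give the consensus interval retained by each copy
#'   (full length for active copies).
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "te_family_spec"))
  withr::with_seed(spec$seed, {
    core_len <- spec$consensus_length - 2L * spec$tir_length
    left_tir <- random_dna(spec$tir_length)
    core <- random_dna(core_len)
    if (!is.null(spec$orf_codons)) {
      # plant ATG + (orf_codons - 1) non-stop codons + TAA shortly after the
      # left TIR (core coordinates), so ORF recovery has a known truth
      orf <- paste0(
        "ATG",
        paste(sample(non_stop_codons(), spec$orf_codons - 1L, replace = TRUE),
              collapse = ""),
        "TAA"
      )
      at <- 11L
      core <- paste0(
        substr(core, 1L, at - 1L),
        orf,
        substr(core, at + nchar(orf), core_len)
      )
    }
    consensus <- paste0(left_tir, core, revcomp(left_tir))

    strains <- names(spec$n_active_copies)
    active <- purrr::map_dfr(strains, function(s) {
      n <- spec$n_active_copies[[s]]
      if (n == 0) return(NULL)
      tibble::tibble(
        copy_id = sprintf("%s_%s_active_%02d", spec$family_id, s, seq_len(n)),
        class = "active",
        strain = s,
        divergence = spec$active_divergence,
        c_start = 1L,
        c_end = spec$consensus_length,
        sequence = vapply(seq_len(n),
                          function(i) mutate_dna(consensus, spec$active_divergence),
                          character(1))
      )
    })

    degraded <- NULL
    if (spec$n_degraded_copies > 0) {
      dv <- stats::runif(spec$n_degraded_copies,
                         spec$degraded_divergence_range[1],
                         spec$degraded_divergence_range[2])
      fr <- stats::runif(spec$n_degraded_copies,
                         spec$truncation_fraction_range[1],
                         spec$truncation_fraction_range[2])
      keep_len <- pmax(1L, as.integer(round(fr * spec$consensus_length)))
      from_left <- sample(c(TRUE, FALSE), spec$n_degraded_copies, replace = TRUE)
      c_start <- ifelse(from_left, 1L, spec$consensus_length - keep_len + 1L)
      c_end <- c_start + keep_len - 1L
      degraded <- tibble::tibble(
        copy_id = sprintf("%s_degraded_%02d", spec$family_id,
                          seq_len(spec$n_degraded_copies)),
        class = "degraded",
        strain = "shared",
        divergence = dv,
        c_start = as.integer(c_start),
        c_end = as.integer(c_end),
        sequence = vapply(seq_len(spec$n_degraded_copies), function(i) {
          mutate_dna(substr(consensus, c_start[i], c_end[i]), dv[i])
        }, character(1))
      )
    }

    copies <- dplyr::bind_rows(active, degraded)
    if (nrow(copies) > 0) copies$length <- nchar(copies$sequence)

    structure(
      list(consensus = consensus, copies = copies, spec = spec),
      class = "te_family_sim"
    )
  })
}

#' Build synthetic strain genomes with a truth table
#'
#' Inserts the simulated copies of one or more families into a shared random
#' background sequence at uniformly drawn, non-overlapping insertion points
#' on random strands. Degraded copies are shared between strains (same copy
#' sequences, independently placed); active copies are strain-specific per
#' each family's spec.
#'
#' @param families List of [te_family_spec()] or `te_family_sim` objects.
#' @param background_length Length of the TE-free background in bp.
#' @param seed Integer seed for placement and background.
#' @return A list of class `te_genome_set`: `genomes` (named character vector
#'   of strain sequences), `insertions` (truth tibble with `strain`,
#'   `family_id`, `copy_id`, `class`, `start`, `end`, `strand`; 1-based
#'   inclusive coordinates in the strain genome), `library` (tibble
#'   `family_id`, `consensus`), `background_length`, `seed`.
#' @export
build_genomes <- function(families, background_length, seed = 1L) {
  if (inherits(families, c("te_family_spec", "te_family_sim"))) families <- list(families)
  sims <- purrr::map(families, function(f) {
    if (inherits(f, "te_family_spec")) simulate_family(f) else f
  })
  stopifnot(all(purrr::map_lgl(sims, inherits, "te_family_sim")))
  total_inserted <- sum(purrr::map_dbl(sims, function(s) {
    if (nrow(s$copies) == 0) 0 else sum(nchar(s$copies$sequence))
  }))
  if (background_length <= total_inserted) {
    stop("background_length must exceed the total inserted copy length")
  }
  strains <- unique(unlist(purrr::map(sims, ~ names(.x$spec$n_active_copies))))

  withr::with_seed(seed, {
    background <- random_dna(background_length)
    genomes <- character(0)
    truth <- list()
    for (s in strains) {
      copies <- purrr::map_dfr(sims, function(sim) {
        cp <- sim$copies
        if (nrow(cp) == 0) return(NULL)
        cp <- cp[cp$strain %in% c(s, "shared"), , drop = FALSE]
        if (nrow(cp) == 0) return(NULL)
        cp$family_id <- sim$spec$family_id
        cp
      })
      if (nrow(copies) == 0) {
        genomes[s] <- background
        next
      }
      n <- nrow(copies)
      # insertion points between background bases: overlap is impossible
      points <- sort(sample.int(background_length - 1L, n, replace = FALSE))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      inserted <- ifelse(strand == "+", copies$sequence, revcomp(copies$sequence))
      lens <- nchar(inserted)
      offsets <- c(0, cumsum(lens))[seq_len(n)]
      start <- points + offsets + 1L
      end <- start + lens - 1L
      pieces <- character(2L * n + 1L)
      prev <- 1L
      for (i in seq_len(n)) {
        pieces[2L * i - 1L] <- substr(background, prev, points[i])
        pieces[2L * i] <- inserted[i]
        prev <- points[i] + 1L
      }
      pieces[2L * n + 1L] <- substr(background, prev, background_length)
      genomes[s] <- paste(pieces, collapse = "")
      truth[[s]] <- tibble::tibble(
        strain = s,
        family_id = copies$family_id,
        copy_id = copies$copy_id,
        class = copies$class,
        start = as.integer(start),
        end = as.integer(end),
        strand = strand
      )
    }
    structure(
      list(
        genomes = genomes,
        insertions = dplyr::bind_rows(truth),
        library = tibble::tibble(
          family_id = purrr::map_chr(sims, ~ .x$spec$family_id),
          consensus = purrr::map_chr(sims, "consensus")
        ),
        sims = sims,
        background_length = as.integer(background_length),
        seed = as.integer(seed)
      ),
      class = "te_genome_set"
    )
  })
}

#' Simulate single-end short reads from a genome
#'
#' Uniform start positions on random strands, per-base substitution errors
#' (to one of the three alternative bases), constant Phred+33 base quality,
#' and an optional fraction of reads carrying a low-quality 3' tail (for
#' exercising the quality-trimming filters).
#'
#' @param genome A single DNA string (or a `te_genome_set` plus `strain`).
#' @param mean_coverage Fold coverage; number of reads is
#'   `round(mean_coverage * genome_length / read_length)`.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error probability.
#' @param base_quality Phred score written for every base.
#' @param tail_prob Fraction of reads given a low-quality 3' tail.
#' @param tail_max Maximum tail length in bp.
#' @param tail_quality Phred score of tail bases.
#' @param strain_label Label used in read ids and the `strain` column.
#' @param strain When `genome` is a `te_genome_set`, which strain to draw from.
#' @param seed Integer seed.
#' @return A tibble of class `te_read_set` with columns `read_id`, `strain`,
#'   `sequence`, `quality`, `true_start`, `true_end`, `true_strand` (truth
#'   interval on the genome, 1-based inclusive).
#' @export
simulate_reads <- function(genome, mean_coverage, read_length = 100L,
                           error_rate = 0.001, base_quality = 35L,
                           tail_prob = 0, tail_max = 0L, tail_quality = 10L,
                           strain_label = "strain", strain = NULL, seed = 1L) {
  if (inherits(genome, "te_genome_set")) {
    stopifnot(!is.null(strain))
    strain_label <- strain
    genome <- genome$genomes[[strain]]
  }
  glen <- nchar(genome)
  stopifnot(mean_coverage > 0, read_length >= 1, read_length <= glen,
            error_rate >= 0, error_rate < 1)
  n <- as.integer(round(mean_coverage * glen / read_length))
  withr::with_seed(seed, {
    starts <- sample.int(glen - read_length + 1L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genome, starts, starts + read_length - 1L)
    minus <- strand == "-"
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    if (error_rate > 0) {
      err <- which(stats::runif(n * read_length) < error_rate)
      if (length(err) > 0) {
        ridx <- ((err - 1L) %/% read_length) + 1L
        pos <- ((err - 1L) %% read_length) + 1L
        for (j in seq_along(err)) {
          old <- substr(seqs[ridx[j]], pos[j], pos[j])
          substr(seqs[ridx[j]], pos[j], pos[j]) <-
            sample(setdiff(DNA_BASES, old), 1L)
        }
      }
    }
    qual <- rep(strrep(int_to_qual(base_quality), read_length), n)
    if (tail_prob > 0 && tail_max > 0) {
      tailed <- which(stats::runif(n) < tail_prob)
      if (length(tailed) > 0) {
        tl <- sample.int(tail_max, length(tailed), replace = TRUE)
        for (j in seq_along(tailed)) {
          i <- tailed[j]
          qual[i] <- paste0(
            substr(qual[i], 1L, read_length - tl[j]),
            strrep(int_to_qual(tail_quality), tl[j])
          )
        }
      }
    }
    out <- tibble::tibble(
      read_id = sprintf("%s_read_%07d", strain_label, seq_len(n)),
      strain = strain_label,
      sequence = seqs,
      quality = qual,
      true_start = as.integer(starts),
      true_end = as.integer(starts + read_length - 1L),
      true_strand = strand
    )
    class(out) <- c("te_read_set", class(out))
    out
  })
}

#' Specify a reciprocal-cross expression design
#'
#' A 2 (treatment: dysgenic vs non-dysgenic) x 2 (age class) factorial in
#' which each RNA sample yields two index (barcode) libraries, each sequenced
#' on two lanes: 16 observations. Barcodes are drawn from three labels,
#' varying within treatment x age cells, so the barcode term carries 2
#' degrees of freedom and the residual 10 -- the structure of the published
#' ANOVA tables this package's sequential ANOVA reproduces.
#'
#' @param baseline Mean RPM of the non-dysgenic, young cell.
#' @param treatment_effect Added mean RPM in dysgenic samples.
#' @param age_effect Added mean RPM in the older age class.
#' @param interaction_effect Added mean RPM in dysgenic x older samples.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return An object of class `te_expression_design`.
#' @export
expression_design <- function(baseline = 10, treatment_effect = 0,
                              age_effect = 0, interaction_effect = 0,
                              noise_sd = 1, seed = 1L) {
  stopifnot(noise_sd >= 0)
  structure(
    list(
      baseline = baseline, treatment_effect = treatment_effect,
      age_effect = age_effect, interaction_effect = interaction_effect,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "te_expression_design"
  )
}

#' Simulate a per-library RPM expression table
#'
#' @param design An [expression_design()].
#' @return A tibble with 16 rows and columns `library_id`, `treatment`,
#'   `age_class`, `barcode`, `lane`, `rpm`.
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "te_expression_design"))
  cells <- tidyr::expand_grid(
    treatment = c("non-dysgenic", "dysgenic"),
    age_class = c("12-16d", "19-21d")
  )
  # two index libraries per cell, barcodes from a pool of three labels,
  # varying within cells (df = 2, not confounded with treatment or age)
  barcode_pairs <- list(c("B1", "B2"), c("B1", "B3"), c("B2", "B3"), c("B1", "B2"))
  libs <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    tibble::tibble(
      treatment = cells$treatment[i],
      age_class = cells$age_class[i],
      barcode = barcode_pairs[[i]]
    )
  })
  obs <- tidyr::expand_grid(libs, lane = c("L1", "L2"))
  obs$library_id <- sprintf("lib_%02d", rep(seq_len(8), each = 2))
  mu <- design$baseline +
    design$treatment_effect * (obs$treatment == "dysgenic") +
    design$age_effect * (obs$age_class == "19-21d") +
    design$interaction_effect *
      (obs$treatment == "dysgenic" & obs$age_class == "19-21d")
  withr::with_seed(design$seed, {
    obs$rpm <- mu + stats::rnorm(nrow(obs), 0, design$noise_sd)
  })
  dplyr::select(obs, "library_id", "treatment", "age_class", "barcode", "lane", "rpm")
}
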