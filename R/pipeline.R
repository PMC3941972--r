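#' Run the two-strain enrichment + heterogeneity screen
#'
#' End-to-end composition of the screening stages: quality trim/filter both
#' strains' reads, assign them to the repeat library, build the normalized
#' count table and chi-squared enrichment report, profile per-site coverage
#' and major-variant frequency for screened families, and call candidates.
#' A family is a candidate when its fold ratio (in either direction) is at
#' least `fold_threshold`, its chi-squared p-value is below `p_threshold`,
#' and its profile is active-like in exactly one strain.
#'
#' When no `denominators` are supplied, total QC-surviving reads per strain
#' are used as the normalization denominator and the report's
#' `denominator_source` records the substitution (the reference-genome
#' mapped-read count is the preferred denominator when available).
#'
#' @param reads_a,reads_b Read tibbles for the two strains.
#' @param library Repeat library tibble (`family_id`, `consensus`).
#' @param strain_labels Length-2 character vector naming the strains
#'   (a then b; the fold ratio is a:b).
#' @param qc A [qc_params()].
#' @param k Seed length for read assignment.
#' @param min_identity,min_aligned_fraction Passed to [assign_reads()].
#' @param denominators Optional tibble (`strain`, `mapped_reads`).
#' @param fold_threshold,p_threshold Candidate thresholds.
#' @param h_threshold,min_depth Profile classification parameters.
#' @param pseudocount Passed to [fold_enrichment()].
#' @return A list of class `te_screen`: `enrichment` (per-family report),
#'   `profiles` (long per-site tibble for screened families),
#'   `activity` ([activity_summary()] output), `candidates` (tibble of
#'   candidate families), `qc_summary`, `assignments`, `denominators`,
#'   `denominator_source`, `manifest`, `params`.
#' @export
run_screen <- function(reads_a, reads_b, library,
                       strain_labels = c("strainA", "strainB"),
                       qc = qc_params(), k = 15L,
                       min_identity = 0.85, min_aligned_fraction = 0.5,
                       denominators = NULL,
                       fold_threshold = 10, p_threshold = 0.001,
                       h_threshold = 0.95, min_depth = 4L,
                       pseudocount = 0) {
  stopifnot(length(strain_labels) == 2)
  qa <- qc_reads(reads_a, qc)
  qb <- qc_reads(reads_b, qc)
  qc_summary <- dplyr::bind_rows(
    dplyr::mutate(qa$summary, strain = strain_labels[1], .before = 1),
    dplyr::mutate(qb$summary, strain = strain_labels[2], .before = 1)
  )
  denominator_source <- "mapped_reads (supplied)"
  if (is.null(denominators)) {
    denominators <- tibble::tibble(
      strain = strain_labels,
      mapped_reads = c(qa$summary$n_kept, qb$summary$n_kept)
    )
    denominator_source <- "total QC-surviving reads (no reference genome supplied)"
  }
  idx <- kmer_index(library, k = k)
  asg_a <- assign_reads(qa$reads, idx, min_identity, min_aligned_fraction)
  asg_b <- assign_reads(qb$reads, idx, min_identity, min_aligned_fraction)
  assignments <- dplyr::bind_rows(
    dplyr::mutate(asg_a, strain = strain_labels[1], .before = 1),
    dplyr::mutate(asg_b, strain = strain_labels[2], .before = 1)
  )
  counts <- count_table(assignments, denominators,
                        families = library$family_id)
  enr <- enrichment_report(counts, strain_labels, pseudocount)
  ratio_max <- pmax(enr$fold, 1 / enr$fold)
  screened <- enr$family_id[
    !is.na(ratio_max) & ratio_max >= fold_threshold &
      !is.na(enr$p_value) & enr$p_value < p_threshold
  ]
  profiles <- purrr::map_dfr(screened, function(fam) {
    cons <- library$consensus[library$family_id == fam]
    purrr::map_dfr(strain_labels, function(s) {
      site_profile(
        assignments[assignments$strain == s, , drop = FALSE],
        cons, family = fam,
        mapped_reads = denominators$mapped_reads[denominators$strain == s],
        min_depth = min_depth, strain = s
      )
    })
  })
  activity <- if (nrow(profiles) > 0) {
    activity_summary(profiles, h_threshold)
  } else {
    activity_summary(
      tibble::tibble(strain = character(0), family_id = character(0),
                     coverage_per_million = numeric(0),
                     major_fraction = numeric(0))
    )
  }
  n_active_like <- activity |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      n_active_like = sum(.data$classification == "active-like"),
      .groups = "drop"
    )
  candidates <- enr |>
    dplyr::filter(.data$family_id %in% screened) |>
    dplyr::inner_join(n_active_like, by = "family_id") |>
    dplyr::filter(.data$n_active_like == 1)
  manifest <- tibble::tibble(
    stage = c("qc", "assign", "enrich", "profile"),
    n_in = c(nrow(reads_a) + nrow(reads_b),
             sum(qc_summary$n_kept),
             nrow(assignments),
             length(screened)),
    n_out = c(sum(qc_summary$n_kept),
              sum(!is.na(assignments$family_id)),
              nrow(enr),
              nrow(candidates))
  )
  structure(
    list(
      enrichment = enr, profiles = profiles, activity = activity,
      candidates = candidates, qc_summary = qc_summary,
      assignments = assignments, denominators = denominators,
      denominator_source = denominator_source, manifest = manifest,
      params = list(
        strain_labels = strain_labels, k = k, min_identity = min_identity,
        min_aligned_fraction = min_aligned_fraction,
        fold_threshold = fold_threshold, p_threshold = p_threshold,
        h_threshold = h_threshold, min_depth = min_depth,
        pseudocount = pseudocount, qc = qc
      )
    ),
    class = "te_screen"
  )
}

#' @export
print.te_screen <- function(x, ...) {
  cat("Two-strain TE screen (", paste(x$params$strain_labels, collapse = " vs "),
      ")\n", sep = "")
  cat("  families tested:   ", nrow(x$enrichment), "\n", sep = "")
  cat("  candidates:        ",
      paste(x$candidates$family_id, collapse = ", "), "\n", sep = "")
  cat("  denominator:       ", x$denominator_source, "\n", sep = "")
  invisible(x)
}

#' Characterize a candidate element in a genome
#'
#' Composition of the characterization stages for one family: copy
#' extraction and core consensus, TIR and ORF annotation, fragment
#' collection, neighbor-joining tree and molecular-clock ages, and (when
#' expression observations are supplied) the sequential ANOVA.
#'
#' @param genome Genome DNA string (the strain carrying active copies, or a
#'   reference known to carry them).
#' @param query Consensus of the candidate family (e.g. its library entry).
#' @param expression Optional expression observation tibble for
#'   [sequential_anova()].
#' @param flank Flank length for copy extraction.
#' @param n_copies Copies used for the core consensus.
#' @param fragment_min_identity,fragment_min_length Fragment collection
#'   thresholds.
#' @param exclude_tir Exclude TIR-only fragments from dating.
#' @param substitution_rate,generations_per_year Clock parameters.
#' @param ... Further arguments passed to [annotate_element()].
#' @return A list of class `te_characterization`: `annotation`
#'   (`te_annotation`), `ages` (`te_age_result`), `anova` (`te_anova` or
#'   NULL), `manifest`.
#' @export
run_characterize <- function(genome, query, expression = NULL,
                             flank = 1000L, n_copies = 3L,
                             fragment_min_identity = 0.6,
                             fragment_min_length = 100L,
                             exclude_tir = TRUE,
                             substitution_rate = 1.45e-9,
                             generations_per_year = 10, ...) {
  ann <- annotate_element(genome, query, flank = flank, n_copies = n_copies,
                          ...)
  dating_query <- if (!is.null(ann$core) && nchar(ann$core$core) >= 100) {
    ann$core$core
  } else {
    query
  }
  tir <- if (!is.null(ann$tir) && nrow(ann$tir) == 1) ann$tir else NULL
  ages <- fragment_ages(
    genome, dating_query,
    min_identity = fragment_min_identity,
    min_length = fragment_min_length,
    exclude_tir = exclude_tir, tir = tir,
    substitution_rate = substitution_rate,
    generations_per_year = generations_per_year
  )
  anova_res <- if (!is.null(expression)) sequential_anova(expression) else NULL
  manifest <- tibble::tibble(
    stage = c("annotate", "collect_fragments", "tree_and_ages", "anova"),
    n_in = c(1L, nchar(dating_query),
             nrow(ages$fragments$fragments),
             if (is.null(expression)) 0L else nrow(expression)),
    n_out = c(nrow(ann$copies),
              nrow(ages$fragments$fragments),
              if (is.null(ages$ages)) 0L else nrow(ages$ages),
              if (is.null(anova_res)) 0L else nrow(anova_res$table))
  )
  structure(
    list(annotation = ann, ages = ages, anova = anova_res,
         manifest = manifest),
    class = "te_characterization"
  )
}

#' @export
print.te_characterization <- function(x, ...) {
  cat("TE characterization\n")
  cat("  copies extracted:  ", nrow(x$annotation$copies), "\n", sep = "")
  if (!is.null(x$annotation$core)) {
    cat("  core length:       ", nchar(x$annotation$core$core), " bp\n", sep = "")
  }
  if (!is.null(x$annotation$tir) && nrow(x$annotation$tir) == 1) {
    cat("  TIR length:        ", x$annotation$tir$length, " bp (identity ",
        round(x$annotation$tir$identity, 3), ")\n", sep = "")
  }
  if (!is.null(x$ages$ages)) {
    cat("  fragments dated:   ", nrow(x$ages$ages), "\n", sep = "")
  }
  invisible(x)
}
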