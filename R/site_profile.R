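#' Per-position base counts from assigned reads
#'
#' Each aligned read base increments the count of its base at its consensus
#' position; minus-strand reads contribute reverse-complemented bases
#' (already stored in consensus-forward orientation by [assign_reads()]).
#' `N` bases are excluded from counts. Substitution-only alignments: the four
#' base counts sum to the depth at every position.
#'
#' @param assignments Assignment tibble for one family (rows with
#'   `family_id`, `c_start`, `aligned_seq`; unassigned rows are ignored).
#' @param consensus The family consensus sequence (defines profile length).
#' @param family Optional family id to filter `assignments` to.
#' @return A tibble with columns `pos`, `A`, `C`, `G`, `T`, `depth`, one row
#'   per consensus position.
#' @export
pileup_profile <- function(assignments, consensus, family = NULL) {
  len <- nchar(consensus)
  a <- assignments[!is.na(assignments$family_id), , drop = FALSE]
  if (!is.null(family)) a <- a[a$family_id == family, , drop = FALSE]
  counts <- matrix(0L, nrow = 4, ncol = len,
                   dimnames = list(DNA_BASES, NULL))
  if (nrow(a) > 0) {
    if (any(a$c_start < 1 | a$c_start + nchar(a$aligned_seq) - 1 > len)) {
      stop("assignment interval out of consensus bounds")
    }
    lens <- nchar(a$aligned_seq)
    chars <- unlist(strsplit(a$aligned_seq, "", fixed = TRUE), use.names = FALSE)
    pos <- sequence(lens, from = a$c_start)
    code <- match(chars, DNA_BASES)
    keep <- !is.na(code)
    idx <- (pos[keep] - 1L) * 4L + code[keep]
    tab <- tabulate(idx, nbins = 4L * len)
    counts[] <- tab
  }
  tibble::tibble(
    pos = seq_len(len),
    A = counts["A", ], C = counts["C", ], G = counts["G", ], T = counts["T", ],
    depth = as.integer(colSums(counts))
  )
}

#' Major-variant frequency profile
#'
#' At each position, `h = max(base count) / sum(base counts)`: the frequency
#' of the most common aligned base, regardless of whether it matches the
#' consensus. Positions with depth below `min_depth` are masked (`NA`).
#' Values near 1 indicate a homogeneous (recently active, single-lineage)
#' copy population; lower values indicate divergent lineages.
#'
#' @param pileup A [pileup_profile()] tibble.
#' @param min_depth Minimum depth for `h` to be defined.
#' @return Numeric vector `h` of length `nrow(pileup)`.
#' @export
heterogeneity_profile <- function(pileup, min_depth = 4L) {
  m <- as.matrix(pileup[, DNA_BASES])
  tot <- rowSums(m)
  h <- ifelse(tot >= min_depth & tot > 0, apply(m, 1, max) / tot, NA_real_)
  as.numeric(h)
}

#' Depth profile normalized per million mapped reads
#'
#' `c = 1e6 * depth / mapped_reads`.
#'
#' @param pileup A [pileup_profile()] tibble.
#' @param mapped_reads Mapped-read denominator of the strain (> 0).
#' @return Numeric vector of normalized coverage.
#' @export
coverage_profile <- function(pileup, mapped_reads) {
  if (mapped_reads <= 0) stop("mapped_reads must be positive")
  1e6 * pileup$depth / mapped_reads
}

#' Full per-site profile for one family in one strain
#'
#' Combines [pileup_profile()], [coverage_profile()] and
#' [heterogeneity_profile()] into the per-position table the screen plots.
#'
#' @param assignments Assignment tibble (with `strain` column optional).
#' @param consensus Family consensus sequence.
#' @param family Family id.
#' @param mapped_reads Denominator for coverage normalization.
#' @param min_depth Minimum depth for the major-variant frequency.
#' @param strain Optional strain label recorded in the output.
#' @return A tibble: `strain`, `family_id`, `pos`, `A`, `C`, `G`, `T`,
#'   `depth`, `coverage_per_million`, `major_fraction`.
#' @export
site_profile <- function(assignments, consensus, family, mapped_reads,
                         min_depth = 4L, strain = NA_character_) {
  p <- pileup_profile(assignments, consensus, family = family)
  tibble::tibble(
    strain = strain,
    family_id = family,
    p,
    coverage_per_million = coverage_profile(p, mapped_reads),
    major_fraction = heterogeneity_profile(p, min_depth)
  )
}

#' Summarize activity state per strain and family
#'
#' Mean defined major-variant frequency and median normalized coverage, with
#' an active-like / degraded-like call: active-like iff the mean defined `h`
#' is at least `h_threshold`. Families with no defined positions are
#' unclassified.
#'
#' @param profiles One or more [site_profile()] tibbles bound by rows.
#' @param h_threshold Mean-h cutoff for the active-like call.
#' @return A tibble: `strain`, `family_id`, `n_defined`, `mean_h`,
#'   `median_coverage`, `classification`.
#' @export
activity_summary <- function(profiles, h_threshold = 0.95) {
  profiles |>
    dplyr::group_by(.data$strain, .data$family_id) |>
    dplyr::summarise(
      n_defined = sum(!is.na(.data$major_fraction)),
      mean_h = if (any(!is.na(.data$major_fraction))) {
        mean(.data$major_fraction, na.rm = TRUE)
      } else NA_real_,
      median_coverage = stats::median(.data$coverage_per_million),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      classification = dplyr::case_when(
        .data$n_defined == 0 ~ "unclassified",
        .data$mean_h >= h_threshold ~ "active-like",
        TRUE ~ "degraded-like"
      )
    )
}
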