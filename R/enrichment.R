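#' Build a k-mer index over a repeat-consensus library
#'
#' Every length-`k` substring of every consensus, on both strands, keyed for
#' exact lookup. Minus-strand entries index the reverse complement of the
#' consensus; their positions are stored in reverse-complement coordinates
#' and converted back when an assignment is reported.
#'
#' @param library A tibble with columns `family_id` (unique) and `consensus`
#'   (DNA over A/C/G/T/N, each at least `k` long).
#' @param k Seed length in bp (>= 8).
#' @return An object of class `te_kmer_index`.
#' @export
kmer_index <- function(library, k = 15L) {
  stopifnot(all(c("family_id", "consensus") %in% names(library)),
            !anyDuplicated(library$family_id), k >= 8)
  if (any(nchar(library$consensus) < k)) {
    stop("k exceeds the length of the shortest consensus")
  }
  k <- as.integer(k)
  entries <- purrr::map_dfr(seq_len(nrow(library)), function(i) {
    cons <- library$consensus[i]
    len <- nchar(cons)
    pos <- seq_len(len - k + 1L)
    rc <- revcomp(cons)
    dplyr::bind_rows(
      tibble::tibble(kmer = substring(cons, pos, pos + k - 1L),
                     family_id = library$family_id[i], pos = pos, strand = "+"),
      tibble::tibble(kmer = substring(rc, pos, pos + k - 1L),
                     family_id = library$family_id[i], pos = pos, strand = "-")
    )
  })
  consensi <- stats::setNames(library$consensus, library$family_id)
  structure(
    list(entries = entries, k = k,
         consensi = consensi,
         rc_consensi = stats::setNames(revcomp(library$consensus), library$family_id)),
    class = "te_kmer_index"
  )
}

#' Look up a k-mer in the index
#'
#' @param index A [kmer_index()].
#' @param kmer A single k-mer string.
#' @return A tibble of hits (`family_id`, `pos`, `strand`); zero rows when
#'   absent. Minus-strand positions are in reverse-complement coordinates.
#' @export
kmer_hits <- function(index, kmer) {
  stopifnot(inherits(index, "te_kmer_index"), nchar(kmer) == index$k)
  index$entries[index$entries$kmer == kmer, c("family_id", "pos", "strand")]
}

# mismatches between a read segment and a reference segment, both plain strings
segment_identity <- function(read_seg, ref_seg) {
  len <- nchar(ref_seg)
  (len - count_mismatches(read_seg, ref_seg)) / len
}

#' Assign reads to repeat families by seeded gapless alignment
#'
#' Seeds (non-overlapping k-mers of each read) are looked up in the library
#' index; each seeded (family, strand, offset) candidate is scored by a full
#' gapless comparison of the read against the consensus at that offset,
#' clipped at consensus ends. The best candidate wins by identity, ties
#' broken by longer aligned length, then lexicographically smallest
#' family_id. Reads below `min_identity` or `min_aligned_fraction`, or with
#' no seed hit, are unassigned (`family_id = NA`).
#'
#' @param reads Read tibble (`read_id`, `sequence`; other columns ignored).
#' @param index A [kmer_index()].
#' @param min_identity Minimum identity over the aligned interval.
#' @param min_aligned_fraction Minimum fraction of the read aligned (only
#'   reads overhanging a consensus end align partially).
#' @return A tibble with one row per read: `read_id`, `family_id` (`NA` if
#'   unassigned), `c_start` (1-based start on the consensus forward strand),
#'   `strand`, `identity`, `aligned_length`, `aligned_seq` (the aligned read
#'   bases in consensus-forward orientation, for pileups).
#' @export
assign_reads <- function(reads, index, min_identity = 0.85,
                         min_aligned_fraction = 0.5) {
  stopifnot(inherits(index, "te_kmer_index"),
            all(c("read_id", "sequence") %in% names(reads)))
  k <- index$k
  empty <- tibble::tibble(
    read_id = character(0), family_id = character(0), c_start = integer(0),
    strand = character(0), identity = numeric(0), aligned_length = integer(0),
    aligned_seq = character(0)
  )
  if (nrow(reads) == 0) return(empty)
  rl <- nchar(reads$sequence)
  if (any(rl < k)) stop("all reads must be at least k bases long")

  # non-overlapping seeds plus one flush with the 3' end
  seed_tbl <- purrr::map_dfr(unique(rl), function(len) {
    sp <- unique(c(seq(1L, len - k + 1L, by = k), len - k + 1L))
    idx <- which(rl == len)
    tibble::tibble(
      read_idx = rep(idx, each = length(sp)),
      seedpos = rep(sp, times = length(idx))
    )
  })
  seed_tbl$kmer <- substring(reads$sequence[seed_tbl$read_idx],
                             seed_tbl$seedpos, seed_tbl$seedpos + k - 1L)
  hits <- dplyr::inner_join(seed_tbl, index$entries, by = "kmer",
                            relationship = "many-to-many")
  out <- tibble::tibble(
    read_id = reads$read_id, family_id = NA_character_, c_start = NA_integer_,
    strand = NA_character_, identity = NA_real_, aligned_length = NA_integer_,
    aligned_seq = NA_character_
  )
  if (nrow(hits) == 0) return(out)

  # candidate alignments: read start on the (strand-specific) consensus
  cand <- dplyr::distinct(
    tibble::tibble(
      read_idx = hits$read_idx,
      family_id = hits$family_id,
      strand = hits$strand,
      s = hits$pos - (hits$seedpos - 1L)
    )
  )
  refs <- ifelse(cand$strand == "+",
                 unname(index$consensi[cand$family_id]),
                 unname(index$rc_consensi[cand$family_id]))
  ref_len <- nchar(refs)
  read_len <- rl[cand$read_idx]
  ov_start <- pmax(1L, cand$s)
  ov_end <- pmin(ref_len, cand$s + read_len - 1L)
  alen <- ov_end - ov_start + 1L
  ok <- alen >= k
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(out)
  refs <- refs[ok]; ref_len <- ref_len[ok]; read_len <- read_len[ok]
  ov_start <- ov_start[ok]; ov_end <- ov_end[ok]; alen <- alen[ok]

  read_seg <- substr(reads$sequence[cand$read_idx],
                     ov_start - cand$s + 1L, ov_end - cand$s + 1L)
  ref_seg <- substr(refs, ov_start, ov_end)
  mm <- mapply(count_mismatches, read_seg, ref_seg, USE.NAMES = FALSE)
  cand$identity <- (alen - mm) / alen
  cand$aligned_length <- alen
  cand$ov_start <- ov_start
  cand$ref_len <- ref_len
  cand$read_seg <- read_seg

  cand <- cand[cand$identity >= min_identity &
                 alen >= min_aligned_fraction * read_len, , drop = FALSE]
  if (nrow(cand) == 0) return(out)
  best <- cand |>
    dplyr::arrange(.data$read_idx, dplyr::desc(.data$identity),
                   dplyr::desc(.data$aligned_length), .data$family_id) |>
    dplyr::distinct(.data$read_idx, .keep_all = TRUE)

  # report on consensus forward coordinates; minus-strand aligned bases are
  # reverse-complemented into forward orientation
  minus <- best$strand == "-"
  c_start <- best$ov_start
  aligned_seq <- best$read_seg
  if (any(minus)) {
    c_start[minus] <- best$ref_len[minus] -
      (best$ov_start[minus] + best$aligned_length[minus] - 1L) + 1L
    aligned_seq[minus] <- revcomp(best$read_seg[minus])
  }
  out$family_id[best$read_idx] <- best$family_id
  out$c_start[best$read_idx] <- c_start
  out$strand[best$read_idx] <- best$strand
  out$identity[best$read_idx] <- best$identity
  out$aligned_length[best$read_idx] <- best$aligned_length
  out$aligned_seq[best$read_idx] <- aligned_seq
  out
}

#' Aggregate assignments into a per-strain, per-family count table
#'
#' @param assignments Assignment tibble(s) with a `strain` column (bind rows
#'   of per-strain [assign_reads()] output after adding `strain`).
#' @param denominators Tibble with `strain` and `mapped_reads`: the
#'   normalization denominator per strain (reads mapped to the reference
#'   genome, or total QC-surviving reads when no genome is available).
#' @param families Optional character vector of family ids to report
#'   (zero-filled); defaults to families observed in the assignments.
#' @return A tibble with columns `strain`, `family_id`, `n_reads`,
#'   `mapped_reads`.
#' @export
count_table <- function(assignments, denominators, families = NULL) {
  stopifnot(all(c("strain", "family_id") %in% names(assignments)),
            all(c("strain", "mapped_reads") %in% names(denominators)))
  strains <- unique(assignments$strain)
  missing <- setdiff(strains, denominators$strain)
  if (length(missing) > 0) {
    stop("missing denominator for strain(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(families)) {
    families <- sort(unique(stats::na.omit(assignments$family_id)))
  }
  counts <- assignments |>
    dplyr::filter(!is.na(.data$family_id)) |>
    dplyr::count(.data$strain, .data$family_id, name = "n_reads") |>
    tidyr::complete(
      strain = denominators$strain,
      family_id = families,
      fill = list(n_reads = 0L)
    ) |>
    dplyr::left_join(denominators[, c("strain", "mapped_reads")], by = "strain")
  if (any(counts$n_reads > counts$mapped_reads)) {
    stop("family read count exceeds its strain's mapped-read denominator")
  }
  counts
}

#' Normalize counts to reads per million mapped
#'
#' `rpm = 1e6 * n_reads / mapped_reads`.
#'
#' @param counts A [count_table()] tibble.
#' @return The input with an added `rpm` column.
#' @export
rpm_normalize <- function(counts) {
  if (any(counts$mapped_reads <= 0)) stop("mapped_reads must be positive")
  dplyr::mutate(counts, rpm = 1e6 * .data$n_reads / .data$mapped_reads)
}

#' Per-family fold enrichment between two strains
#'
#' `R = (rpm_a + pseudocount) / (rpm_b + pseudocount)`. With the default
#' pseudocount of 0, a zero in only the denominator gives `Inf` and a zero in
#' both gives `NA` (undefined).
#'
#' @param normalized Output of [rpm_normalize()].
#' @param strain_pair Length-2 character vector `(a, b)`; the ratio is a:b.
#' @param pseudocount Added to both normalized counts before the ratio.
#' @return A tibble with `family_id`, `rpm_a`, `rpm_b`, `fold`.
#' @export
fold_enrichment <- function(normalized, strain_pair, pseudocount = 0) {
  stopifnot(length(strain_pair) == 2, "rpm" %in% names(normalized))
  wide <- normalized |>
    dplyr::filter(.data$strain %in% strain_pair) |>
    dplyr::select("strain", "family_id", "rpm") |>
    tidyr::pivot_wider(names_from = "strain", values_from = "rpm")
  a <- wide[[strain_pair[1]]] + pseudocount
  b <- wide[[strain_pair[2]]] + pseudocount
  fold <- dplyr::if_else(a == 0 & b == 0, NA_real_, a / b)
  tibble::tibble(family_id = wide$family_id,
                 rpm_a = wide[[strain_pair[1]]],
                 rpm_b = wide[[strain_pair[2]]],
                 fold = fold)
}

#' Two-strain chi-squared test of family read abundance
#'
#' Pearson chi-squared (1 df, no continuity correction) on the 2x2 table
#' `[[r1, M1 - r1], [r2, M2 - r2]]`: reads of the family versus all other
#' mapped reads, by strain. Vectorized over families.
#'
#' @param r1,r2 Family read counts in strains 1 and 2.
#' @param M1,M2 Mapped-read denominators.
#' @return A tibble with `statistic` and `p_value` (`NA` when a table margin
#'   is zero and the test is undefined).
#' @export
chisq_enrichment <- function(r1, M1, r2, M2) {
  stopifnot(all(r1 <= M1), all(r2 <= M2), all(r1 >= 0), all(r2 >= 0))
  n <- max(length(r1), length(r2))
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n)
  M1 <- rep_len(M1, n); M2 <- rep_len(M2, n)
  res <- purrr::map(seq_len(n), function(i) {
    tab <- matrix(c(r1[i], M1[i] - r1[i], r2[i], M2[i] - r2[i]),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(c(NA_real_, NA_real_))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    c(unname(ct$statistic), unname(ct$p.value))
  })
  tibble::tibble(
    statistic = purrr::map_dbl(res, 1),
    p_value = purrr::map_dbl(res, 2)
  )
}

#' Full enrichment report for a strain pair
#'
#' Normalized counts, fold ratio, and chi-squared test per family: the
#' cross-strain abundance screen.
#'
#' @param counts A [count_table()] tibble.
#' @param strain_pair Length-2 character vector `(a, b)`.
#' @param pseudocount Passed to [fold_enrichment()].
#' @return A tibble with one row per family: counts, `rpm_a`/`rpm_b`, `fold`,
#'   `statistic`, `p_value`.
#' @export
enrichment_report <- function(counts, strain_pair, pseudocount = 0) {
  norm <- rpm_normalize(counts)
  fe <- fold_enrichment(norm, strain_pair, pseudocount)
  wide_n <- counts |>
    dplyr::filter(.data$strain %in% strain_pair) |>
    dplyr::select("strain", "family_id", "n_reads", "mapped_reads") |>
    tidyr::pivot_wider(names_from = "strain",
                       values_from = c("n_reads", "mapped_reads"))
  r1 <- wide_n[[paste0("n_reads_", strain_pair[1])]]
  r2 <- wide_n[[paste0("n_reads_", strain_pair[2])]]
  M1 <- wide_n[[paste0("mapped_reads_", strain_pair[1])]]
  M2 <- wide_n[[paste0("mapped_reads_", strain_pair[2])]]
  chi <- chisq_enrichment(r1, M1, r2, M2)
  out <- tibble::tibble(
    family_id = wide_n$family_id,
    n_reads_a = r1, n_reads_b = r2,
    mapped_reads_a = M1, mapped_reads_b = M2
  ) |>
    dplyr::left_join(fe, by = "family_id") |>
    dplyr::bind_cols(chi)
  attr(out, "strain_pair") <- strain_pair
  out
}

#' Sequencing fold-coverage estimate
#'
#' `C = read_pairs * ends_per_pair * read_length / genome_size`.
#'
#' @param read_pairs Number of read pairs sequenced.
#' @param read_length Read length in bp.
#' @param ends_per_pair Sequenced ends per pair (2 for paired-end).
#' @param genome_size Genome size in bp.
#' @return Fold coverage (numeric).
#' @export
coverage_estimate <- function(read_pairs, read_length, ends_per_pair = 2,
                              genome_size) {
  stopifnot(read_pairs > 0, read_length > 0, ends_per_pair > 0)
  if (genome_size <= 0) stop("genome_size must be positive")
  read_pairs * ends_per_pair * read_length / genome_size
}
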