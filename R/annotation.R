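#' Find local matches of a query sequence in a subject
#'
#' Desk-scale stand-in for a local aligner: exact k-mer seeds on both
#' strands are chained along diagonals (substitution-only, so matches stay on
#' one diagonal) and extended outward until a run of `stop_run` consecutive
#' mismatches, then trimmed back to the outermost matching bases. Suitable
#' for finding degraded, truncated copies of a consensus in a genome.
#'
#' @param subject Subject DNA string (e.g. a genome).
#' @param query Query DNA string (e.g. a consensus).
#' @param k Seed length.
#' @param min_length Minimum reported match length in bp.
#' @param min_identity Minimum identity of the reported match.
#' @param max_gap Maximum seed-to-seed gap (bp) within one chain.
#' @param xdrop Score drop (match +1, mismatch -3) that terminates extension;
#'   the reported boundary is the position of the running score maximum.
#' @return A tibble with columns `s_start`, `s_end` (subject, 1-based
#'   inclusive), `q_start`, `q_end` (query forward coordinates), `strand`,
#'   `length`, `identity`.
#' @export
find_local_matches <- function(subject, query, k = 12L, min_length = 50L,
                               min_identity = 0, max_gap = 200L,
                               xdrop = 20L) {
  stopifnot(nchar(query) >= k, nchar(subject) >= k)
  k <- as.integer(k)
  qlen <- nchar(query)
  slen <- nchar(subject)
  rcq <- revcomp(query)
  qpos <- seq_len(qlen - k + 1L)
  q_tbl <- dplyr::bind_rows(
    tibble::tibble(kmer = substring(query, qpos, qpos + k - 1L),
                   qpos = qpos, strand = "+"),
    tibble::tibble(kmer = substring(rcq, qpos, qpos + k - 1L),
                   qpos = qpos, strand = "-")
  )
  spos <- seq_len(slen - k + 1L)
  s_tbl <- tibble::tibble(kmer = substring(subject, spos, spos + k - 1L),
                          spos = spos)
  hits <- dplyr::inner_join(s_tbl, q_tbl, by = "kmer",
                            relationship = "many-to-many")
  empty <- tibble::tibble(
    s_start = integer(0), s_end = integer(0), q_start = integer(0),
    q_end = integer(0), strand = character(0), length = integer(0),
    identity = numeric(0)
  )
  if (nrow(hits) == 0) return(empty)
  hits$diag <- hits$spos - hits$qpos
  sub_raw <- charToRaw(subject)
  q_raw <- list("+" = charToRaw(query), "-" = charToRaw(rcq))

  groups <- split(hits, interaction(hits$strand, hits$diag, drop = TRUE))
  out <- purrr::map_dfr(groups, function(g) {
    st <- g$strand[1]
    dg <- g$diag[1]
    sp <- sort(unique(g$spos))
    cl_id <- cumsum(c(1L, diff(sp) > max_gap))
    purrr::map_dfr(split(sp, cl_id), function(cs) {
      core_lo <- min(cs)
      core_hi <- max(cs) + k - 1L
      # maximal subject extent reachable on this diagonal
      ext_lo <- max(1L, dg + 1L)
      ext_hi <- min(slen, dg + qlen)
      m <- sub_raw[ext_lo:ext_hi] == q_raw[[st]][(ext_lo:ext_hi) - dg]
      lo_i <- core_lo - ext_lo + 1L
      hi_i <- core_hi - ext_lo + 1L
      # X-drop extension right: boundary sits at the running score maximum
      score <- 0L; best <- 0L; best_i <- hi_i
      i <- hi_i
      while (i < length(m)) {
        i <- i + 1L
        score <- score + if (m[i]) 1L else -3L
        if (score > best) {
          best <- score; best_i <- i
        } else if (best - score >= xdrop) break
      }
      hi_i <- best_i
      # X-drop extension left
      score <- 0L; best <- 0L; best_i <- lo_i
      i <- lo_i
      while (i > 1L) {
        i <- i - 1L
        score <- score + if (m[i]) 1L else -3L
        if (score > best) {
          best <- score; best_i <- i
        } else if (best - score >= xdrop) break
      }
      lo_i <- best_i
      len <- hi_i - lo_i + 1L
      ident <- sum(m[lo_i:hi_i]) / len
      s_start <- ext_lo + lo_i - 1L
      s_end <- ext_lo + hi_i - 1L
      qa <- s_start - dg
      qb <- s_end - dg
      if (st == "-") {
        tmp <- qa
        qa <- qlen - qb + 1L
        qb <- qlen - tmp + 1L
      }
      tibble::tibble(s_start = s_start, s_end = s_end, q_start = qa,
                     q_end = qb, strand = st, length = len, identity = ident)
    })
  })
  if (nrow(out) == 0 || ncol(out) == 0) return(empty)
  out <- dplyr::distinct(out, .data$s_start, .data$s_end, .data$strand,
                         .keep_all = TRUE)
  out <- out[out$length >= min_length & out$identity >= min_identity, ,
             drop = FALSE]
  dplyr::arrange(out, .data$s_start)
}

#' Extract genomic copies of a query with flanking sequence
#'
#' Local matches of `query` in `genome` above the identity and length
#' thresholds are extracted with up to `flank` bp on each side (clipped at
#' sequence ends); minus-strand hits are reverse-complemented so every
#' extraction carries the copy in query orientation.
#'
#' @param genome Genome DNA string.
#' @param query Query (consensus) DNA string.
#' @param flank Flank length in bp.
#' @param min_identity,min_length Hit thresholds.
#' @param k Seed length for the local matcher.
#' @return A tibble: `copy_id`, `g_start`, `g_end`, `strand`, `identity`,
#'   `flank_left`, `flank_right` (realized flank lengths in extraction
#'   orientation), `sequence`.
#' @export
extract_copies_with_flanks <- function(genome, query, flank = 1000L,
                                       min_identity = 0.85, min_length = 100L,
                                       k = 12L) {
  stopifnot(nchar(query) > 0)
  hits <- find_local_matches(genome, query, k = k, min_length = min_length,
                             min_identity = min_identity)
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      copy_id = character(0), g_start = integer(0), g_end = integer(0),
      strand = character(0), identity = numeric(0), flank_left = integer(0),
      flank_right = integer(0), sequence = character(0)
    ))
  }
  glen <- nchar(genome)
  ext_start <- pmax(1L, hits$s_start - as.integer(flank))
  ext_end <- pmin(glen, hits$s_end + as.integer(flank))
  seqs <- substring(genome, ext_start, ext_end)
  fl <- hits$s_start - ext_start
  fr <- ext_end - hits$s_end
  minus <- hits$strand == "-"
  if (any(minus)) {
    seqs[minus] <- revcomp(seqs[minus])
    tmp <- fl[minus]
    fl[minus] <- fr[minus]
    fr[minus] <- tmp
  }
  tibble::tibble(
    copy_id = sprintf("copy_%02d", seq_len(nrow(hits))),
    g_start = hits$s_start, g_end = hits$s_end, strand = hits$strand,
    identity = hits$identity,
    flank_left = as.integer(fl), flank_right = as.integer(fr),
    sequence = seqs
  )
}

#' Core consensus shared by near-identical copies
#'
#' Reciprocal pairwise comparison of flanked copies: the core is the maximal
#' interval, in the first copy's coordinates, covered by a high-identity
#' local alignment in every other copy. The consensus base at each core
#' position is the majority across copies, ties resolved to the first copy's
#' base. Copies are assumed substitution-only relative to each other (no
#' indels), as produced by [extract_copies_with_flanks()] on simulated or
#' recently amplified elements.
#'
#' @param copies Character vector of flanked copy sequences (or the tibble
#'   from [extract_copies_with_flanks()]), at least 2.
#' @param min_identity Identity threshold for a pairwise alignment to count.
#' @param k Seed length for the local matcher.
#' @return A list of class `te_core`: `core` (consensus string, `""` when no
#'   shared interval exists), `start`/`end` (core interval on copy 1), and
#'   `n_copies`.
#' @export
core_consensus <- function(copies, min_identity = 0.9, k = 12L) {
  if (is.data.frame(copies)) copies <- copies$sequence
  stopifnot(length(copies) >= 2)
  ref <- copies[1]
  maps <- purrr::map(copies[-1], function(cp) {
    h <- find_local_matches(cp, ref, k = k, min_length = k,
                            min_identity = min_identity)
    if (nrow(h) == 0) return(NULL)
    h <- h[which.max(h$length), , drop = FALSE]
    if (h$strand == "-") {
      cp <- revcomp(cp)
      h <- find_local_matches(cp, ref, k = k, min_length = k,
                              min_identity = min_identity)
      h <- h[which.max(h$length), , drop = FALSE]
    }
    list(seq = cp, q_start = h$q_start, q_end = h$q_end,
         offset = h$s_start - h$q_start)
  })
  if (any(purrr::map_lgl(maps, is.null))) {
    return(structure(list(core = "", start = NA_integer_, end = NA_integer_,
                          n_copies = length(copies)), class = "te_core"))
  }
  lo <- max(purrr::map_int(maps, ~ as.integer(.x$q_start)))
  hi <- min(purrr::map_int(maps, ~ as.integer(.x$q_end)))
  if (hi < lo) {
    return(structure(list(core = "", start = NA_integer_, end = NA_integer_,
                          n_copies = length(copies)), class = "te_core"))
  }
  core_len <- hi - lo + 1L
  chm <- matrix("", nrow = length(copies), ncol = core_len)
  chm[1, ] <- seq_chars(substr(ref, lo, hi))
  for (i in seq_along(maps)) {
    mp <- maps[[i]]
    chm[i + 1L, ] <- seq_chars(substr(mp$seq, lo + mp$offset, hi + mp$offset))
  }
  score <- vapply(DNA_BASES, function(b) colSums(chm == b), numeric(core_len))
  if (core_len == 1L) score <- matrix(score, nrow = 1)
  # tie-break to copy 1's base: give it a sub-integer bonus
  ref_code <- match(chm[1, ], DNA_BASES)
  score[cbind(seq_len(core_len), ref_code)] <-
    score[cbind(seq_len(core_len), ref_code)] + 0.5
  cons <- DNA_BASES[max.col(score)]
  structure(
    list(core = paste(cons, collapse = ""), start = lo, end = hi,
         n_copies = length(copies)),
    class = "te_core"
  )
}

# terminal match score series for one (left offset, right offset) pair:
# returns best TIR candidate under a match/mismatch score, or NULL
tir_candidate <- function(s, min_len, min_identity, mismatch_penalty = 3) {
  len <- nchar(s)
  half <- len %/% 2L
  if (half < min_len) return(NULL)
  t <- revcomp(s)
  m <- charToRaw(substr(s, 1L, half)) == charToRaw(substr(t, 1L, half))
  cm <- cumsum(m)
  l <- seq_len(half)
  ident <- cm / l
  score <- cm - mismatch_penalty * (l - cm)
  ok <- l >= min_len & ident >= min_identity
  if (!any(ok)) return(NULL)
  best <- which(ok)[which.max(score[ok])]
  list(length = best, identity = ident[best], score = score[best])
}

#' Detect terminal inverted repeats
#'
#' Aligns the 5' terminal region against the reverse complement of the 3'
#' terminal region, anchored at the sequence ends with a small offset
#' allowance, and reports the highest-scoring terminal match of length at
#' least `min_len` with identity at least `min_identity` (match +1,
#' mismatch -3, no gaps). Absence of a TIR is a value, not an error.
#'
#' @param sequence Element DNA string.
#' @param min_len Minimum TIR length in bp.
#' @param min_identity Minimum identity of the two arms.
#' @param max_offset Maximum bp by which either arm may be recessed from its
#'   terminus.
#' @return A one-row tibble (`length`, `identity`, `left_start`, `left_end`,
#'   `right_start`, `right_end`) or a zero-row tibble when none is found.
#' @export
detect_tir <- function(sequence, min_len = 20L, min_identity = 0.8,
                       max_offset = 10L) {
  stopifnot(nchar(sequence) >= 2 * min_len)
  len <- nchar(sequence)
  best <- NULL
  for (lo in 0:max_offset) {
    for (ro in 0:max_offset) {
      sub <- substr(sequence, 1L + lo, len - ro)
      cand <- tir_candidate(sub, min_len, min_identity)
      if (!is.null(cand) &&
          (is.null(best) || cand$score > best$score)) {
        best <- c(cand, list(lo = lo, ro = ro))
      }
    }
  }
  if (is.null(best)) {
    return(tibble::tibble(
      length = integer(0), identity = numeric(0), left_start = integer(0),
      left_end = integer(0), right_start = integer(0), right_end = integer(0)
    ))
  }
  tibble::tibble(
    length = as.integer(best$length),
    identity = best$identity,
    left_start = 1L + best$lo,
    left_end = best$lo + best$length,
    right_start = len - best$ro - best$length + 1L,
    right_end = len - best$ro
  )
}

#' Find open reading frames in all six frames
#'
#' Scans every frame on both strands for ATG...stop spans of at least
#' `min_codons` codons (excluding the stop). Each maximal ORF (from the
#' first ATG after the previous stop) also reports downstream in-frame ATGs
#' before the stop as alternate translation starts. Standard genetic code.
#'
#' @param sequence DNA string.
#' @param min_codons Minimum number of codons (amino acids) in the ORF.
#' @return A tibble: `strand`, `frame` (0-2 on the reported strand),
#'   `start`, `end` (1-based inclusive on the input's forward strand,
#'   including the stop codon), `n_codons`, `protein`, `alternate_starts`
#'   (list column of forward-strand positions of downstream in-frame ATGs).
#' @export
find_orfs <- function(sequence, min_codons = 50L) {
  stopifnot(min_codons >= 1)
  len <- nchar(sequence)
  gc <- Biostrings::GENETIC_CODE
  scan_strand <- function(s, strand) {
    out <- list()
    for (f in 0:2) {
      n_cod <- (nchar(s) - f) %/% 3L
      if (n_cod < min_codons + 1L) next
      starts_nt <- f + 3L * (seq_len(n_cod) - 1L) + 1L
      codons <- substring(s, starts_nt, starts_nt + 2L)
      aa <- gc[codons]
      aa[is.na(aa)] <- "X"
      stops <- which(aa == "*")
      atgs <- which(codons == "ATG")
      prev_stop <- 0L
      for (st in stops) {
        cand <- atgs[atgs > prev_stop & atgs < st]
        if (length(cand) > 0) {
          a0 <- cand[1]
          n_codons <- st - a0
          if (n_codons >= min_codons) {
            nt_start <- starts_nt[a0]
            nt_end <- starts_nt[st] + 2L
            alt <- starts_nt[cand[-1]]
            if (strand == "-") {
              fs <- len - nt_end + 1L
              fe <- len - nt_start + 1L
              alt <- len - (alt + 2L) + 1L
              nt_start <- fs
              nt_end <- fe
            }
            out[[length(out) + 1L]] <- tibble::tibble(
              strand = strand, frame = f,
              start = as.integer(nt_start), end = as.integer(nt_end),
              n_codons = as.integer(n_codons),
              protein = paste(aa[a0:(st - 1L)], collapse = ""),
              alternate_starts = list(as.integer(alt))
            )
          }
        }
        prev_stop <- st
      }
    }
    dplyr::bind_rows(out)
  }
  res <- dplyr::bind_rows(
    scan_strand(sequence, "+"),
    scan_strand(revcomp(sequence), "-")
  )
  if (nrow(res) == 0) {
    return(tibble::tibble(
      strand = character(0), frame = integer(0), start = integer(0),
      end = integer(0), n_codons = integer(0), protein = character(0),
      alternate_starts = list()
    ))
  }
  dplyr::arrange(res, dplyr::desc(.data$n_codons))
}

#' Global percent identity between two proteins
#'
#' End-to-end (Needleman-Wunsch) alignment under BLOSUM62 with affine gaps;
#' identity is the fraction of alignment columns (including gap columns)
#' where the two residues match.
#'
#' @param query,subject Amino-acid strings.
#' @return Percent identity in `[0, 100]`.
#' @export
protein_identity <- function(query, subject) {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  p <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  s <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  100 * sum(p == s & p != "-") / length(p)
}

#' Annotate an element: core consensus, TIRs, ORFs
#'
#' Convenience composition of [extract_copies_with_flanks()],
#' [core_consensus()], [detect_tir()] and [find_orfs()] for one candidate
#' element in one genome.
#'
#' @param genome Genome DNA string.
#' @param query Query consensus of the candidate family.
#' @param flank Flank length for copy extraction.
#' @param n_copies Number of best (longest) copies used for the core.
#' @param min_identity_extract Identity threshold for copy extraction.
#' @param core_min_identity Identity threshold inside [core_consensus()].
#' @param tir_min_len,tir_min_identity TIR detection thresholds.
#' @param orf_min_codons Minimum ORF length in codons.
#' @return A list of class `te_annotation`: `copies`, `core` (a `te_core`),
#'   `tir`, `orfs`.
#' @export
annotate_element <- function(genome, query, flank = 1000L, n_copies = 3L,
                             min_identity_extract = 0.85,
                             core_min_identity = 0.9,
                             tir_min_len = 20L, tir_min_identity = 0.8,
                             orf_min_codons = 50L) {
  copies <- extract_copies_with_flanks(
    genome, query, flank = flank,
    min_identity = min_identity_extract,
    min_length = max(100L, as.integer(0.5 * nchar(query)))
  )
  copies <- copies |>
    dplyr::arrange(dplyr::desc(.data$g_end - .data$g_start),
                   dplyr::desc(.data$identity)) |>
    dplyr::slice_head(n = n_copies)
  if (nrow(copies) < 2) {
    return(structure(
      list(copies = copies, core = NULL, tir = NULL, orfs = NULL),
      class = "te_annotation"
    ))
  }
  core <- core_consensus(copies, min_identity = core_min_identity)
  tir <- NULL
  orfs <- NULL
  if (nchar(core$core) >= 2 * tir_min_len) {
    tir <- detect_tir(core$core, min_len = tir_min_len,
                      min_identity = tir_min_identity)
    orfs <- find_orfs(core$core, min_codons = orf_min_codons)
  }
  structure(
    list(copies = copies, core = core, tir = tir, orfs = orfs),
    class = "te_annotation"
  )
}
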