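# Shared fixtures, all generated in code under fixed seeds.

# a read tibble from plain sequences with constant quality
make_reads <- function(sequences, quality_int = 35L, ids = NULL) {
  n <- length(sequences)
  if (is.null(ids)) ids <- sprintf("r%03d", seq_len(n))
  tibble::tibble(
    read_id = ids,
    sequence = sequences,
    quality = vapply(nchar(sequences),
                     function(l) strrep(intToUtf8(quality_int + 33L), l),
                     character(1))
  )
}

# a read with an explicit integer quality vector
make_read_q <- function(sequence, quals, id = "r1") {
  tibble::tibble(
    read_id = id,
    sequence = sequence,
    quality = intToUtf8(quals + 33L, multiple = FALSE)
  )
}

# deterministic random DNA
fixture_dna <- function(len, seed) {
  withr::with_seed(seed, tescreen::random_dna(len))
}

# small two-family library used across enrichment tests
fixture_library <- function(seed = 42, len = 300) {
  withr::with_seed(seed, tibble::tibble(
    family_id = c("famA", "famB"),
    consensus = c(tescreen::random_dna(len), tescreen::random_dna(len))
  ))
}

# substitute exactly n positions of a sequence (never back to the original base)
substitute_n <- function(sequence, n, seed = 1) {
  withr::with_seed(seed, {
    chars <- strsplit(sequence, "")[[1]]
    pos <- sample(length(chars), n)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    paste(chars, collapse = "")
  })
}

# brute-force mismatch count between equal-length strings (independent of
# package internals)
brute_mismatches <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

# Smith-Waterman family picker used as the assignment oracle: best local
# alignment score of the read against each family consensus (both strands)
sw_best_family <- function(read, library) {
  scores <- vapply(seq_len(nrow(library)), function(i) {
    cons <- library$consensus[i]
    max(
      Biostrings::pairwiseAlignment(read, cons, type = "local",
                                    substitutionMatrix =
                                      Biostrings::nucleotideSubstitutionMatrix(1, -1),
                                    gapOpening = 4, gapExtension = 1,
                                    scoreOnly = TRUE),
      Biostrings::pairwiseAlignment(tescreen::revcomp(read), cons, type = "local",
                                    substitutionMatrix =
                                      Biostrings::nucleotideSubstitutionMatrix(1, -1),
                                    gapOpening = 4, gapExtension = 1,
                                    scoreOnly = TRUE)
    )
  }, numeric(1))
  list(family = library$family_id[which.max(scores)], scores = scores)
}

# printed ANOVA summary tables (term, df, sum of squares) used as worked
# inputs for the sequential-ANOVA arithmetic
penelope_printed <- function() {
  tibble::tibble(
    term = c("Treat", "Age", "Barcode", "Treat:Age", "Residuals"),
    df = c(1, 1, 2, 1, 10),
    sum_sq = c(26600, 1523.7, 137, 1722.3, 166.8)
  )
}

polyphemus_printed <- function() {
  tibble::tibble(
    term = c("Treat", "Age", "Barcode", "Treat:Age", "Residuals"),
    df = c(1, 1, 2, 1, 10),
    sum_sq = c(24.9251, 0.0564, 0.9773, 0.0039, 5.74)
  )
}
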