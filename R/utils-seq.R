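DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#'
#' Uniform i.i.d. sequence over A/C/G/T. Uses the current RNG state; wrap in
#' [withr::with_seed()] (as the simulators do) for reproducibility.
#'
#' @param length Sequence length in bp.
#' @return A single character string.
#' @export
random_dna <- function(length) {
  stopifnot(length >= 0)
  if (length == 0) return("")
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# mismatch count between equal-length strings; byte comparison
count_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

#' Mutate a DNA sequence by independent per-site substitution
#'
#' Each site is substituted with probability `divergence`; the replacement is
#' drawn uniformly from the three alternative bases (Jukes-Cantor-compatible,
#' no indels).
#'
#' @param sequence DNA string.
#' @param divergence Per-site substitution probability in `[0, 0.75]`.
#' @return Mutated DNA string.
#' @export
mutate_dna <- function(sequence, divergence) {
  stopifnot(divergence >= 0, divergence <= 0.75)
  if (divergence == 0 || nchar(sequence) == 0) return(sequence)
  chars <- seq_chars(sequence)
  hit <- which(stats::runif(length(chars)) < divergence)
  if (length(hit) > 0) {
    chars[hit] <- vapply(
      chars[hit],
      function(b) sample(setdiff(DNA_BASES, b), 1L),
      character(1),
      USE.NAMES = FALSE
    )
  }
  paste(chars, collapse = "")
}

# Phred+33 helpers
qual_to_int <- function(quality) lapply(quality, function(q) utf8ToInt(q) - 33L)

int_to_qual <- function(q) {
  stopifnot(all(q >= 0), all(q <= 93))
  intToUtf8(q + 33L)
}
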