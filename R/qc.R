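#' Quality-control parameters for read trimming and filtering
#'
#' Defaults mirror the RNA-seq cleaning rule the pipeline is built around:
#' up to 16 bp trimmed from the 3' end where quality falls below Q20, then
#' reads with more than 2 remaining bases under Q20 discarded.
#'
#' @param max_3prime_trim Maximum number of bases trimmed from the 3' end.
#' @param qual_threshold Phred score below which a base counts as low quality.
#' @param max_low_qual_bases Maximum number of low-quality bases a kept read
#'   may contain after trimming ("more than this many" is discarded).
#' @param min_length_after_trim Minimum surviving read length.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(max_3prime_trim = 16L, qual_threshold = 20L,
                      max_low_qual_bases = 2L, min_length_after_trim = 25L) {
  stopifnot(
    max_3prime_trim >= 0, qual_threshold >= 0, qual_threshold <= 93,
    max_low_qual_bases >= 0, min_length_after_trim >= 0
  )
  structure(
    list(
      max_3prime_trim = as.integer(max_3prime_trim),
      qual_threshold = as.integer(qual_threshold),
      max_low_qual_bases = as.integer(max_low_qual_bases),
      min_length_after_trim = as.integer(min_length_after_trim)
    ),
    class = "qc_params"
  )
}

# per-read 3' trim length: maximal terminal run of quality < threshold,
# capped at max_3prime_trim
trim_lengths <- function(quality, params) {
  vapply(qual_to_int(quality), function(q) {
    low_rev <- rev(q < params$qual_threshold)
    run <- match(FALSE, low_rev, nomatch = length(q) + 1L) - 1L
    min(run, params$max_3prime_trim)
  }, integer(1))
}

#' Trim low-quality 3' ends from reads
#'
#' Removes the maximal 3'-terminal run of bases whose quality is below
#' `qual_threshold`, capped at `max_3prime_trim` bases. Internal bases are
#' never removed; output reads are prefixes of their inputs.
#'
#' @param reads A tibble with columns `sequence` and `quality` (equal
#'   lengths per read).
#' @param params A [qc_params()].
#' @return The input tibble with `sequence`/`quality` trimmed and an added
#'   `trimmed_bases` column.
#' @export
trim_3prime <- function(reads, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"),
            all(c("sequence", "quality") %in% names(reads)))
  if (nrow(reads) == 0) return(dplyr::mutate(reads, trimmed_bases = integer(0)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence and quality lengths differ for some reads")
  }
  tr <- trim_lengths(reads$quality, params)
  newlen <- nchar(reads$sequence) - tr
  dplyr::mutate(
    reads,
    sequence = substr(.data$sequence, 1L, newlen),
    quality = substr(.data$quality, 1L, newlen),
    trimmed_bases = tr
  )
}

#' Keep/discard decision for trimmed reads
#'
#' A read is discarded iff it has more than `max_low_qual_bases` bases below
#' `qual_threshold`, or is shorter than `min_length_after_trim`.
#'
#' @param reads A tibble with columns `sequence` and `quality`.
#' @param params A [qc_params()].
#' @return Logical vector, `TRUE` for reads to keep.
#' @export
filter_reads <- function(reads, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  if (nrow(reads) == 0) return(logical(0))
  n_low <- vapply(qual_to_int(reads$quality),
                  function(q) sum(q < params$qual_threshold), integer(1))
  n_low <= params$max_low_qual_bases &
    nchar(reads$sequence) >= params$min_length_after_trim
}

#' Trim and filter a batch of reads
#'
#' Applies [trim_3prime()] then [filter_reads()], preserving input order.
#' Idempotent on already-clean reads.
#'
#' @param reads A read tibble (`read_id`, `sequence`, `quality`, other
#'   columns carried through).
#' @param params A [qc_params()].
#' @return A list of class `te_qc_result`: `reads` (survivors) and `summary`
#'   (tibble with `n_input`, `n_trimmed`, `n_discarded`, `n_kept`).
#' @export
qc_reads <- function(reads, params = qc_params()) {
  trimmed <- trim_3prime(reads, params)
  keep <- filter_reads(trimmed, params)
  structure(
    list(
      reads = trimmed[keep, , drop = FALSE],
      summary = tibble::tibble(
        n_input = nrow(reads),
        n_trimmed = sum(trimmed$trimmed_bases > 0),
        n_discarded = sum(!keep),
        n_kept = sum(keep)
      )
    ),
    class = "te_qc_result"
  )
}
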