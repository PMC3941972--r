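#' Read a FASTA file into a tibble
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = names(x), sequence = unname(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param x A tibble with columns `id` and `sequence` (or a named character
#'   vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- tibble::tibble(id = names(x), sequence = unname(x))
  dss <- Biostrings::DNAStringSet(x$sequence)
  names(dss) <- x$id
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path Path to a (possibly gzipped) FASTQ file, Phred+33 qualities.
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    read_id = names(x),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write a read tibble to FASTQ (Phred+33)
#'
#' @param reads A tibble with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  dss <- Biostrings::DNAStringSet(reads$sequence)
  names(dss) <- reads$read_id
  Biostrings::writeXStringSet(
    dss, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality)
  )
  invisible(path)
}

#' Write a result table to TSV with a parameter-snapshot header
#'
#' Writes `# key=value` comment lines (always including the package version)
#' followed by a tab-separated table, so every result file records how it was
#' produced.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param params Named list of parameters to record in the header.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path, params = list()) {
  params <- c(list(package = paste0("tescreen ", utils::packageVersion("tescreen"))), params)
  hdr <- vapply(
    names(params),
    function(k) sprintf("# %s=%s", k, paste(format(params[[k]]), collapse = ",")),
    character(1)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import read-to-family assignments from a SAM/BAM file
#'
#' Entry point for reads mapped by an external aligner against the repeat
#' library: mapped records become rows of the same assignment table produced
#' by [assign_reads()], so they can feed [count_table()] and
#' [pileup_profile()] unchanged. Requires the Rsamtools package.
#'
#' @param path Path to a SAM or BAM file whose reference sequences are repeat
#'   family consensi.
#' @return An assignment tibble with columns `read_id`, `family_id`,
#'   `c_start`, `strand`, `aligned_length`, `aligned_seq` (identity is not
#'   recoverable without the reference and is set to `NA`).
#' @export
import_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("import_sam() requires the Rsamtools package")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(
    path,
    param = Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "strand", "seq"))
  )[[1]]
  keep <- !is.na(b$pos)
  sq <- as.character(b$seq)[keep]
  st <- as.character(b$strand)[keep]
  # SAM stores SEQ already in reference orientation
  tibble::tibble(
    read_id = b$qname[keep],
    family_id = as.character(b$rname)[keep],
    c_start = b$pos[keep],
    strand = st,
    identity = NA_real_,
    aligned_length = nchar(sq),
    aligned_seq = sq
  )
}
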