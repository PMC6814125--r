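#' Read a FASTQ file into a data frame of reads
#'
#' Reads a 4-line FASTQ file (Phred+33) and returns one row per read with the
#' sequence and per-base quality string, the representation the preprocessing
#' functions operate on.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A data frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  # the character conversion drops the object's (unused) metadata columns,
  # which Biostrings reports with a cosmetic warning
  data.frame(
    id = names(x),
    sequence = suppressWarnings(as.character(x)),
    quality = suppressWarnings(as.character(Biostrings::quality(x))),
    stringsAsFactors = FALSE
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  lines <- as.vector(rbind(
    paste0("@", reads$id), reads$sequence, "+", reads$quality
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (DNA alphabet, U converted to T).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(norm_seq(as.character(x)), names(x))
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(norm_seq(seqs)), path)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

#' Published differential-abundance results for the maize root growth zone
#'
#' Returns the published list of water-deficit-regulated miRNAs in the maize
#' primary-root growth zone (mild, -0.3 MPa, and severe, -1.6 MPa, each versus
#' well-watered), with the reported log2 fold change, p-value and FDR. Used as
#' input to [compare_contrasts()] to reproduce the published overlap counts.
#'
#' @return Data frame with columns `mirna_id`, `contrast` (`"mild"`/`"severe"`),
#'   `log2FC`, `pvalue`, `FDR`.
#' @export
reported_de_table <- function() {
  path <- system.file("extdata", "reported_mirna_de.tsv", package = "rootmir")
  read_tsv(path)
}
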