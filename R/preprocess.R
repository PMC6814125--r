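# Read cleaning for small-RNA and degradome libraries: adapter trimming,
# leading-window quality filtering, unique-tag collapsing.

#' Trim a 3' sequencing adapter from reads
#'
#' Truncates each read at the first exact occurrence of the adapter prefix
#' (`min_overlap` bases, default 8). Reads without a match pass through
#' unchanged. Quality strings are truncated alongside the sequence.
#'
#' @param reads Data frame with columns `sequence` and (optionally) `quality`.
#' @param adapter Adapter sequence (3' adapter, given 5'->3').
#' @param min_overlap Minimum adapter prefix length that must match (default 8).
#' @return The reads data frame with trimmed `sequence`/`quality`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8L) {
  stopifnot(nzchar(adapter), min_overlap >= 1L)
  adapter <- norm_seq(adapter)
  probe <- substr(adapter, 1L, min(min_overlap, nchar(adapter)))
  seqs <- norm_seq(reads$sequence)
  pos <- regexpr(probe, seqs, fixed = TRUE)
  hit <- pos > 0L
  keep_len <- ifelse(hit, as.integer(pos) - 1L, nchar(seqs))
  reads$sequence <- substr(seqs, 1L, keep_len)
  if (!is.null(reads$quality)) {
    reads$quality <- substr(reads$quality, 1L, keep_len)
  }
  reads
}

#' Quality-filter reads on their leading window
#'
#' Drops a read if any base among the first `window_nt` has a Phred score
#' strictly below `min_q`. The published rule uses a 25-nt window for
#' small-RNA reads and a 20-nt window for degradome reads. Reads shorter than
#' the window are evaluated over their full length.
#'
#' @param reads Data frame with columns `sequence` and `quality` (Phred+33).
#' @param min_q Minimum acceptable Phred score (default 25; strict `<` drops).
#' @param window_nt Number of leading bases inspected (25 sRNA, 20 degradome).
#' @return The surviving reads.
#' @export
quality_filter <- function(reads, min_q = 25L, window_nt = 25L) {
  if (nrow(reads) == 0L) return(reads)
  qwin <- substr(reads$quality, 1L, window_nt)
  keep <- vapply(qwin, function(q) {
    all(utf8ToInt(q) - 33L >= min_q)
  }, logical(1), USE.NAMES = FALSE)
  reads[keep, , drop = FALSE]
}

#' Collapse reads to unique counted tags
#'
#' Removes reads shorter than `min_len` (18 nt in the published pipeline) and
#' counts each remaining unique sequence once per occurrence.
#'
#' @param reads Data frame with column `sequence` (already trimmed/filtered).
#' @param min_len Minimum tag length retained (default 18).
#' @return Data frame with columns `sequence`, `count`, sorted by decreasing
#'   count; total count equals the number of surviving reads.
#' @export
collapse_unique <- function(reads, min_len = 18L) {
  seqs <- norm_seq(reads$sequence)
  seqs <- seqs[nchar(seqs) >= min_len]
  if (length(seqs) == 0L) {
    return(data.frame(sequence = character(0), count = integer(0)))
  }
  tab <- table(seqs)
  out <- data.frame(
    sequence = names(tab),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract and count degradome tags
#'
#' Degradome (PARE) reads carry the 5' end of an uncapped transcript at their
#' own 5' end; the first 20 nt are the informative cleavage tag. By default the
#' first 20 nt are retained as the tag (`mode = "retain"`). The literal reading
#' of the published processing sentence ("the first 20 nucleotides were
#' removed") is available as `mode = "literal"`, which keeps everything after
#' the first 20 nt instead. Reads too short to yield a tag are dropped.
#'
#' @param reads Data frame of quality-filtered reads (20-nt window).
#' @param tag_len Tag length (default 20).
#' @param mode `"retain"` (default) or `"literal"`, see Details.
#' @return Data frame with columns `sequence`, `count`.
#' @export
degradome_prepare <- function(reads, tag_len = 20L, mode = c("retain", "literal")) {
  mode <- match.arg(mode)
  seqs <- norm_seq(reads$sequence)
  if (mode == "retain") {
    seqs <- seqs[nchar(seqs) >= tag_len]
    tags <- substr(seqs, 1L, tag_len)
  } else {
    seqs <- seqs[nchar(seqs) > tag_len]
    tags <- substr(seqs, tag_len + 1L, nchar(seqs))
  }
  collapse_unique(data.frame(sequence = tags, stringsAsFactors = FALSE),
                  min_len = 1L)
}

#' Run the full small-RNA read-cleaning chain on one library
#'
#' Adapter trimming, leading-25-nt quality filtering (Phred >= 25), removal of
#' reads shorter than 18 nt, and unique-tag counting.
#'
#' @param reads Data frame of raw reads (`id`, `sequence`, `quality`).
#' @param adapter 3' adapter sequence.
#' @param min_q,window_nt,min_len Filter parameters (published defaults).
#' @return Data frame of unique tags with counts.
#' @export
preprocess_srna <- function(reads, adapter, min_q = 25L, window_nt = 25L,
                            min_len = 18L) {
  reads <- quality_filter(reads, min_q = min_q, window_nt = window_nt)
  reads <- trim_adapter(reads, adapter)
  collapse_unique(reads, min_len = min_len)
}

#' Run the degradome read-cleaning chain on one library
#'
#' Leading-20-nt quality filtering (Phred >= 25) followed by 20-nt tag
#' extraction and unique-tag counting.
#'
#' @inheritParams degradome_prepare
#' @param min_q Minimum Phred score (default 25).
#' @return Data frame of unique 20-nt tags with counts.
#' @export
preprocess_degradome <- function(reads, min_q = 25L, tag_len = 20L,
                                 mode = c("retain", "literal")) {
  reads <- quality_filter(reads, min_q = min_q, window_nt = tag_len)
  degradome_prepare(reads, tag_len = tag_len, mode = match.arg(mode))
}
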