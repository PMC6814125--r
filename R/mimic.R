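# Target-mimic (eTM) detection: transcript regions nearly complementary to a
# miRNA but interrupted by a transcript-side insertion bulge at the slicing
# site (the IPS1/pilncr1 architecture), which sequesters the miRNA without
# being cleaved.

#' Scan transcripts for miRNA target-mimic loci
#'
#' Gapped complementarity search: a region of length `M + b` (M = miRNA
#' length) pairs antiparallel with the miRNA except for one transcript-side
#' insertion of `b` (1..`max_insert`) bases placed between the partners of
#' miRNA positions `j+1` and `j` for `j` in 9, 10 - i.e. a bulge opposite the
#' cleavage site (miRNA positions 10-11). At most `max_mismatch_outside`
#' mismatches are allowed among the paired positions. Windows that are
#' perfectly complementary without a bulge are cleavable sites, not mimics,
#' and are excluded.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param mirna miRNA sequence (>= 18 nt).
#' @param mirna_id Id carried into the output.
#' @param max_insert Maximum bulge size in transcript bases (default 3).
#' @param max_mismatch_outside Mismatch budget outside the bulge (default 3).
#' @param gu_policy Wobble handling as in [find_sites()].
#' @param exclude_cleavable Drop zero-bulge perfect-complement windows
#'   (default TRUE; disable only for cross-checking against [find_sites()]).
#' @param collapse_overlaps Collapse overlapping alternative interpretations of
#'   one locus to the best-scoring one (default TRUE).
#' @return Data frame with one row per hit: `transcript_id`, `region_start`,
#'   `region_end` (1-based closed), `mirna_id`, `bulge_after_position` (the
#'   miRNA position 5' of the bulge), `insert_len`, `insert_seq`,
#'   `mismatches_outside_bulge`.
#' @export
scan_mimics <- function(transcripts, mirna, mirna_id = "mirna",
                        max_insert = 3L, max_mismatch_outside = 3,
                        gu_policy = c("mismatch", "match", "half"),
                        exclude_cleavable = TRUE, collapse_overlaps = TRUE) {
  gu_policy <- match.arg(gu_policy)
  pen <- site_penalty_codes(gu_policy)
  mirna <- norm_seq(mirna)
  M <- nchar(mirna)
  stopifnot(M >= 18L)
  rc <- seq_chars(revcomp(mirna))   # rc[k] pairs miRNA position M - k + 1
  hits <- list()
  # max_insert = 0 degenerates to an ungapped scan (used for cross-checking
  # against find_sites)
  inserts <- if (max_insert >= 1L) seq_len(max_insert) else 0L
  for (tid in names(transcripts)) {
    t_ch <- seq_chars(norm_seq(transcripts[[tid]]))
    L <- length(t_ch)
    for (b in inserts) {
      W <- M + b
      if (W > L) next
      for (j in if (b == 0L) 9L else c(9L, 10L)) {
        # region column layout: rc[1 .. M-j] | insert (b) | rc[M-j+1 .. M]
        pre <- M - j
        n_win <- L - W + 1L
        if (n_win < 1L) next
        mm <- numeric(n_win)
        for (k in seq_len(pre)) {
          tb <- t_ch[seq(k, k + n_win - 1L)]
          mm <- mm + pair_penalty(rc[k], tb, pen)
        }
        for (k in seq(pre + 1L, M)) {
          col <- k + b
          tb <- t_ch[seq(col, col + n_win - 1L)]
          mm <- mm + pair_penalty(rc[k], tb, pen)
        }
        ok <- which(mm <= max_mismatch_outside)
        for (s in ok) {
          hits[[length(hits) + 1L]] <- data.frame(
            transcript_id = tid, region_start = s, region_end = s + W - 1L,
            mirna_id = mirna_id,
            bulge_after_position = if (b == 0L) NA_integer_ else j,
            insert_len = b,
            insert_seq = if (b == 0L) "" else
              paste(t_ch[seq(s + pre, s + pre + b - 1L)], collapse = ""),
            mismatches_outside_bulge = mm[s],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    transcript_id = character(0), region_start = integer(0),
    region_end = integer(0), mirna_id = character(0),
    bulge_after_position = integer(0), insert_len = integer(0),
    insert_seq = character(0), mismatches_outside_bulge = numeric(0),
    stringsAsFactors = FALSE
  )
  # collapse alternative interpretations of one locus (overlapping regions on
  # the same transcript): keep the fewest outside-bulge mismatches, then the
  # smallest bulge, then the leftmost start
  if (collapse_overlaps && nrow(out) > 1L) {
    out <- out[order(out$transcript_id, out$mismatches_outside_bulge,
                     out$insert_len, out$region_start), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1L]) {
      prev <- which(keep[seq_len(i - 1L)])
      same <- out$transcript_id[prev] == out$transcript_id[i] &
        out$region_start[prev] <= out$region_end[i] &
        out$region_end[prev] >= out$region_start[i]
      if (any(same)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  if (exclude_cleavable && nrow(out)) {
    perfect <- find_sites_all(setNames(mirna, mirna_id), transcripts,
                              max_mismatch = 0, gu_policy = gu_policy)
    if (nrow(perfect)) {
      drop <- logical(nrow(out))
      for (i in seq_len(nrow(out))) {
        p <- perfect[perfect$transcript_id == out$transcript_id[i], ,
                     drop = FALSE]
        drop[i] <- any(p$site_start >= out$region_start[i] &
                       p$site_end <= out$region_end[i])
      }
      out <- out[!drop, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

pair_penalty <- function(rc_base, t_bases, pen) {
  exact <- t_bases == rc_base
  wob <- (rc_base == "C" & t_bases == "T") | (rc_base == "A" & t_bases == "G")
  ifelse(exact, 0, ifelse(wob, pen[["wobble"]], pen[["other"]]))
}

#' Combine a mimic hit with degradome and differential-abundance evidence
#'
#' Joins a mimic locus with (i) the absence/presence of a valid degradome
#' cleavage call overlapping the locus for the same miRNA and (ii) the
#' transcript's differential-abundance status, the narrative record supporting
#' a sequestering (non-cleaved, stress-induced) mimic.
#'
#' @param hits [scan_mimics()] output.
#' @param target_calls [call_targets()] output (may be empty).
#' @param transcript_de Data frame with columns `transcript_id`, `log2FC`,
#'   `FDR` (transcript-level differential abundance); may be `NULL`.
#' @return `hits` with added columns `cleavage_valid_at_locus`,
#'   `transcript_log2FC`, `transcript_FDR`.
#' @export
mimic_report <- function(hits, target_calls = NULL, transcript_de = NULL) {
  n <- nrow(hits)
  cleaved <- logical(n)
  lfc <- rep(NA_real_, n); fdr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.null(target_calls) && nrow(target_calls)) {
      tc <- target_calls[
        target_calls$transcript_id == hits$transcript_id[i] &
        target_calls$valid &
        target_calls$site_start <= hits$region_end[i] &
        target_calls$site_end >= hits$region_start[i], , drop = FALSE]
      cleaved[i] <- nrow(tc) > 0L
    }
    if (!is.null(transcript_de)) {
      j <- match(hits$transcript_id[i], transcript_de$transcript_id)
      if (!is.na(j)) {
        lfc[i] <- transcript_de$log2FC[j]
        fdr[i] <- transcript_de$FDR[j]
      }
    }
  }
  hits$cleavage_valid_at_locus <- cleaved
  hits$transcript_log2FC <- lfc
  hits$transcript_FDR <- fdr
  hits
}
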