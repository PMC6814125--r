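# Degradome (PARE) target validation: antiparallel binding-site search,
# 5'-end tag pileups, and the two published validity rules (>= 1 read at
# miRNA positions 9-11, fewer than 4 mismatches).

# Per-position penalty between the reverse complement of the miRNA and a
# transcript window. Wobble (G:U) pairs are the cases where the transcript
# base is T opposite a miRNA G (rc base C) or G opposite a miRNA U (rc base A).
site_penalty_codes <- function(gu_policy) {
  switch(gu_policy,
         mismatch = c(wobble = 1, other = 1),
         match = c(wobble = 0, other = 1),
         half = c(wobble = 0.5, other = 1),
         stop("unknown gu_policy"))
}

#' Find miRNA binding sites on a transcript
#'
#' Scans every transcript window of miRNA length for an antiparallel
#' Watson-Crick alignment with at most `max_mismatch` mismatches. miRNA
#' position 1 (5' end) pairs with the 3'-most base of the window, so the
#' transcript base paired to miRNA position `i` of a site starting at `s` is
#' `s + M - i` (M = miRNA length). G:U wobble pairs count as mismatches by
#' default (`gu_policy = "mismatch"`), or as matches (`"match"`) or half
#' mismatches (`"half"`).
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet).
#' @param transcript Transcript sequence.
#' @param max_mismatch Maximum mismatch count (default 3: "fewer than 4").
#' @param gu_policy `"mismatch"` (default), `"match"` or `"half"`.
#' @param mirna_id,transcript_id Optional ids carried into the output.
#' @return Data frame with one row per site: `mirna_id`, `transcript_id`,
#'   `site_start`, `site_end` (1-based closed interval), `mismatch_count`,
#'   `pairing` (per-miRNA-position string of `|` match, `o` wobble, `x`
#'   mismatch, 5'->3' of the miRNA).
#' @export
find_sites <- function(mirna, transcript, max_mismatch = 3,
                       gu_policy = c("mismatch", "match", "half"),
                       mirna_id = "mirna", transcript_id = "transcript") {
  gu_policy <- match.arg(gu_policy)
  pen <- site_penalty_codes(gu_policy)
  mirna <- norm_seq(mirna)
  transcript <- norm_seq(transcript)
  M <- nchar(mirna)
  L <- nchar(transcript)
  empty <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      mismatch_count = numeric(0), pairing = character(0),
                      stringsAsFactors = FALSE)
  if (M > L) return(empty)
  rc <- seq_chars(revcomp(mirna))
  t_ch <- seq_chars(transcript)
  n_win <- L - M + 1L
  mm <- numeric(n_win)
  # status per window x offset, for the pairing string
  status <- matrix("|", n_win, M)
  for (k in seq_len(M)) {
    tb <- t_ch[seq(k, k + n_win - 1L)]
    exact <- tb == rc[k]
    wob <- (rc[k] == "C" & tb == "T") | (rc[k] == "A" & tb == "G")
    pk <- ifelse(exact, 0, ifelse(wob, pen[["wobble"]], pen[["other"]]))
    mm <- mm + pk
    status[!exact & wob, k] <- "o"
    status[!exact & !wob, k] <- "x"
  }
  hit <- which(mm <= max_mismatch)
  if (!length(hit)) return(empty)
  data.frame(
    mirna_id = mirna_id, transcript_id = transcript_id,
    site_start = hit, site_end = hit + M - 1L,
    mismatch_count = mm[hit],
    # window column k pairs miRNA position M - k + 1; report 5'->3' of miRNA
    pairing = apply(status[hit, rev(seq_len(M)), drop = FALSE], 1L,
                    paste, collapse = ""),
    stringsAsFactors = FALSE
  )
}

#' Find binding sites for many miRNAs over many transcripts
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param transcripts Named character vector of transcripts.
#' @inheritParams find_sites
#' @return Row-bound [find_sites()] results.
#' @export
find_sites_all <- function(mirnas, transcripts, max_mismatch = 3,
                           gu_policy = "mismatch") {
  out <- list()
  for (m in names(mirnas)) {
    for (t in names(transcripts)) {
      s <- find_sites(mirnas[[m]], transcripts[[t]], max_mismatch, gu_policy,
                      mirna_id = m, transcript_id = t)
      if (nrow(s)) out[[length(out) + 1L]] <- s
    }
  }
  if (!length(out)) {
    return(find_sites("A", "", mirna_id = "x", transcript_id = "x"))
  }
  do.call(rbind, out)
}

#' Pile up degradome tag 5' ends on transcripts
#'
#' Exact-substring-matches each tag against every transcript and accumulates
#' tag counts at the matched 5'-end positions (1-based). Multi-mapping tags
#' (more than one locus across all transcripts) are counted at every locus and
#' flagged, unless `unique_only = TRUE`.
#'
#' @param tags Data frame with columns `sequence`, `count`.
#' @param transcripts Named character vector of transcript sequences.
#' @param unique_only Drop multi-mapping tags (default FALSE).
#' @return List with `pileups` (named list of per-position count vectors, one
#'   per transcript) and `multi_tags` (sequences that mapped to > 1 locus).
#' @export
pileup_tags <- function(tags, transcripts, unique_only = FALSE) {
  pile <- lapply(transcripts, function(t) numeric(nchar(t)))
  multi <- character(0)
  if (nrow(tags)) {
    seqs <- norm_seq(tags$sequence)
    hits <- vector("list", length(seqs))
    n_loci <- integer(length(seqs))
    for (i in seq_along(seqs)) {
      h <- list()
      for (t in names(transcripts)) {
        p <- gregexpr(seqs[i], transcripts[[t]], fixed = TRUE)[[1]]
        if (p[1] > 0L) h[[t]] <- as.integer(p)
      }
      hits[[i]] <- h
      n_loci[i] <- sum(lengths(h))
    }
    for (i in seq_along(seqs)) {
      if (n_loci[i] == 0L) next
      if (n_loci[i] > 1L) {
        multi <- c(multi, seqs[i])
        if (unique_only) next
      }
      for (t in names(hits[[i]])) {
        for (p in hits[[i]][[t]]) {
          pile[[t]][p] <- pile[[t]][p] + tags$count[i]
        }
      }
    }
  }
  list(pileups = pile, multi_tags = unique(multi))
}

#' Tabulate a pre-mapped degradome tag table into pileups
#'
#' @param tag_table Data frame `transcript_id`, `position`, `count`.
#' @param transcripts Named character vector of transcripts.
#' @return List as in [pileup_tags()].
#' @export
pileup_from_table <- function(tag_table, transcripts) {
  pile <- lapply(transcripts, function(t) numeric(nchar(t)))
  for (i in seq_len(nrow(tag_table))) {
    t <- tag_table$transcript_id[i]
    p <- tag_table$position[i]
    if (!t %in% names(pile)) stop("unknown transcript: ", t)
    if (p < 1L || p > length(pile[[t]])) stop("position outside transcript")
    pile[[t]][p] <- pile[[t]][p] + tag_table$count[i]
  }
  list(pileups = pile, multi_tags = character(0))
}

#' Validate miRNA targets from binding sites and degradome pileups
#'
#' Applies the published validity rule: a site is a valid target when at least
#' one degradome tag 5' end falls on a transcript base paired to miRNA
#' positions 9-11 and the site has fewer than 4 mismatches. Sites are also
#' categorized by the cleavage signal: `dominant-peak` when the strongest
#' 9-11 signal equals the transcript-wide modal 5'-end count (uniquely),
#' `co-dominant` when tied with a position outside 9-11, `minor` otherwise.
#'
#' @param sites Data frame from [find_sites()] / [find_sites_all()].
#' @param pileups List from [pileup_tags()] / [pileup_from_table()].
#' @return `sites` with added columns `valid_reads_9_11`,
#'   `total_reads_in_site`, `peak_position`, `category`, `valid`.
#' @export
call_targets <- function(sites, pileups) {
  pile <- pileups$pileups
  n <- nrow(sites)
  v911 <- numeric(n); tot <- numeric(n)
  peak <- integer(n); cat <- character(n)
  for (i in seq_len(n)) {
    t <- sites$transcript_id[i]
    if (!t %in% names(pile)) stop("site references unknown transcript: ", t)
    p <- pile[[t]]
    s <- sites$site_start[i]; e <- sites$site_end[i]
    M <- e - s + 1L
    pos911 <- s + M - c(9L, 10L, 11L)        # bases paired to positions 9-11
    pos911 <- pos911[pos911 >= 1L & pos911 <= length(p)]
    v911[i] <- sum(p[pos911])
    tot[i] <- sum(p[s:e])
    peak[i] <- which.max(p)
    tmax <- max(p)
    m911 <- if (length(pos911)) max(p[pos911]) else 0
    if (tmax == 0 || m911 < tmax) {
      cat[i] <- "minor"
    } else {
      at_max <- which(p == tmax)
      cat[i] <- if (all(at_max %in% pos911)) "dominant-peak" else "co-dominant"
    }
  }
  sites$valid_reads_9_11 <- v911
  sites$total_reads_in_site <- tot
  sites$peak_position <- peak
  sites$category <- cat
  sites$valid <- v911 >= 1 & sites$mismatch_count < 4
  sites
}

#' Text t-plot of a degradome pileup around a site
#'
#' @param pileups List from [pileup_tags()].
#' @param transcript_id Transcript to plot.
#' @return Data frame `position`, `count` for nonzero positions.
#' @export
tplot_table <- function(pileups, transcript_id) {
  p <- pileups$pileups[[transcript_id]]
  if (is.null(p)) stop("unknown transcript: ", transcript_id)
  nz <- which(p > 0)
  data.frame(position = nz, count = p[nz])
}
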