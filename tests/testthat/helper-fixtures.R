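# Shared fixtures and independent brute-force oracles used across the suite.

make_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs), function(l) {
      paste(rep("I", l), collapse = "")  # Q40
    }, character(1))
  }
  data.frame(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             quality = quals, stringsAsFactors = FALSE)
}

qual_string <- function(scores) intToUtf8(scores + 33L)

tiny_reference <- function(seed = 42) {
  make_reference(sim_config(n_families = 4, members_per_family = 2,
                            n_transcripts = 6, n_target_sites = 3,
                            transcript_length = c(300L, 500L), seed = seed))
}

# brute-force BH step-up, written independently of stats::p.adjust
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# brute-force antiparallel site scan counting non-Watson-Crick pairs
# (G:U wobble counted as mismatch)
brute_sites <- function(mirna, transcript, max_mismatch = 3) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(gsub("U", "T", toupper(mirna)), "")[[1]]
  t <- strsplit(gsub("U", "T", toupper(transcript)), "")[[1]]
  M <- length(m); L <- length(t)
  out <- NULL
  if (M > L) return(integer(0))
  for (s in 1:(L - M + 1)) {
    mm <- 0
    for (i in 1:M) {
      # miRNA position i pairs transcript base s + M - i
      if (t[s + M - i] != comp[[m[i]]]) mm <- mm + 1
    }
    if (mm <= max_mismatch) out <- c(out, s)
  }
  if (is.null(out)) integer(0) else out
}

# brute-force degradome validity: >= 1 tag 5' end at the bases paired to
# miRNA positions 9-11 AND < 4 mismatches
brute_valid <- function(site_start, M, mismatches, pile) {
  pos <- site_start + M - c(9L, 10L, 11L)
  pos <- pos[pos >= 1 & pos <= length(pile)]
  sum(pile[pos]) >= 1 && mismatches < 4
}

# brute-force retention rule: >= min_rptm in >= min_libs libraries of some group
brute_retained <- function(rptm_row, groups, min_rptm = 1, min_libs = 3) {
  any(vapply(unique(groups), function(g) {
    sum(rptm_row[groups == g] >= min_rptm) >= min_libs
  }, logical(1)))
}
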