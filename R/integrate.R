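# Joins miRNA differential abundance, degradome target calls and transcript
# differential abundance into coherence classes, and correlates sequencing
# with qPCR fold-change estimates.

#' Classify degradome-valid miRNA-transcript pairs into coherence classes
#'
#' For each degradome-valid pair: `inverse-correlated` when both miRNA and
#' transcript are significant (FDR < `alpha`) with opposite fold-change signs,
#' `positive-correlated` when both are significant with the same sign, and
#' `target-unchanged` when the transcript is not significant. Pairs whose
#' miRNA or transcript has no differential-abundance record get class `NA`.
#'
#' @param pairs Data frame with columns `mirna_id`, `transcript_id`.
#' @param mirna_de Data frame `mirna_id`, `log2FC`, `FDR`.
#' @param transcript_de Data frame `transcript_id`, `log2FC`, `FDR`.
#' @param alpha FDR significance threshold (default 0.05).
#' @return List with `pairs` (classified data frame) and `counts` (class
#'   table).
#' @export
classify_coherence <- function(pairs, mirna_de, transcript_de, alpha = 0.05) {
  n <- nrow(pairs)
  cls <- rep(NA_character_, n)
  m_lfc <- rep(NA_real_, n); m_fdr <- rep(NA_real_, n)
  t_lfc <- rep(NA_real_, n); t_fdr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    im <- match(pairs$mirna_id[i], mirna_de$mirna_id)
    it <- match(pairs$transcript_id[i], transcript_de$transcript_id)
    if (is.na(im) || is.na(it)) next
    m_lfc[i] <- mirna_de$log2FC[im]; m_fdr[i] <- mirna_de$FDR[im]
    t_lfc[i] <- transcript_de$log2FC[it]; t_fdr[i] <- transcript_de$FDR[it]
    if (t_fdr[i] >= alpha) {
      cls[i] <- "target-unchanged"
    } else if (m_fdr[i] < alpha) {
      cls[i] <- if (sign(m_lfc[i]) == sign(t_lfc[i])) {
        "positive-correlated"
      } else {
        "inverse-correlated"
      }
    }
    # transcript significant but miRNA not: outside the coherence-class
    # universe (which pairs water-deficit-responsive miRNAs with their
    # targets); left NA
  }
  pairs$mirna_log2FC <- m_lfc; pairs$mirna_FDR <- m_fdr
  pairs$transcript_log2FC <- t_lfc; pairs$transcript_FDR <- t_fdr
  pairs$class <- cls
  list(pairs = pairs, counts = table(factor(
    cls, levels = c("target-unchanged", "positive-correlated",
                    "inverse-correlated"))))
}

#' Spearman correlation between platform fold-change estimates
#'
#' Rank correlation (average ranks on ties) between paired log fold-change
#' estimates, e.g. sequencing versus stem-loop RT-qPCR. P-values are exact for
#' small samples without ties and asymptotic otherwise.
#'
#' @param logfc_a,logfc_b Paired numeric vectors (>= 5 values).
#' @return List with `rho` and `p`.
#' @export
cross_platform_correlation <- function(logfc_a, logfc_b) {
  stopifnot(length(logfc_a) == length(logfc_b))
  n <- length(logfc_a)
  if (n < 5L) stop("need at least 5 paired values")
  if (length(unique(logfc_a)) == 1L || length(unique(logfc_b)) == 1L) {
    stop("rank correlation undefined for a constant vector")
  }
  ties <- anyDuplicated(logfc_a) || anyDuplicated(logfc_b)
  ct <- suppressWarnings(stats::cor.test(
    logfc_a, logfc_b, method = "spearman",
    exact = (n <= 10L && !ties)))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
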