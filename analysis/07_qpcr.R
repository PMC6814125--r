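#!/usr/bin/env Rscript
# Step 7: qPCR reference selection, ddCt relative abundance, and the
# cross-platform (sequencing vs qPCR) rank correlation.

library(rootmir)

sim <- file.path("results", "sim")
ct <- read.delim(file.path(sim, "qpcr_ct.tsv"))
truth <- read.delim(file.path(sim, "counts_truth.tsv"))
de_severe <- read.delim(file.path("results", "de_severe.tsv"))

candidates <- truth$id[truth$is_reference]
refs <- select_reference(ct, candidates)
cat("selected references:", paste(refs, collapse = ", "), "\n")

rq <- ddct(ct, refs, calibrator = "WW")
write.table(rq, file.path("results", "qpcr_rq.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sv <- rq[rq$treatment == "severe", ]
common <- intersect(sv$target_id, de_severe$mirna_id)
if (length(common) >= 5) {
  seq_lfc <- de_severe$log2FC[match(common, de_severe$mirna_id)]
  qpcr_lfc <- log2(sv$RQ[match(common, sv$target_id)])
  corr <- cross_platform_correlation(seq_lfc, qpcr_lfc)
  cat(sprintf("sequencing vs qPCR (severe, n = %d): rho = %.3f, p = %.2e\n",
              length(common), corr$rho, corr$p))
}
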