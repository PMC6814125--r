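#!/usr/bin/env Rscript
# Step 6: scan for target-mimic loci and join with degradome evidence.

library(rootmir)

sim <- file.path("results", "sim")
reference <- read.delim(file.path(sim, "reference.tsv"))
transcripts <- read_fasta(file.path(sim, "transcripts.fa"))
calls <- read.delim(file.path("results", "target_calls.tsv"))
truth <- read.delim(file.path(sim, "mimic_locus.tsv"))

mir <- reference$mature[reference$id == truth$mirna_id]
hits <- scan_mimics(transcripts, mir, mirna_id = truth$mirna_id)
report <- mimic_report(hits, calls)
write.table(report, file.path("results", "mimic_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d mimic locus/loci found for %s\n", nrow(hits), truth$mirna_id))
if (nrow(report)) {
  cat(sprintf("planted locus recovered: %s; cleavage-valid at locus: %s\n",
              any(report$transcript_id == truth$transcript_id &
                  report$region_start == truth$region_start),
              any(report$cleavage_valid_at_locus)))
}
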