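#!/usr/bin/env Rscript
# Step 5: binding-site scan, degradome tag pileups and target validation.

library(rootmir)

sim <- file.path("results", "sim")
reference <- read.delim(file.path(sim, "reference.tsv"))
transcripts <- read_fasta(file.path(sim, "transcripts.fa"))
deg_tags <- read.delim(file.path("results", "degradome_tags.tsv"))

mirs <- setNames(reference$mature, reference$id)
sites <- find_sites_all(mirs, transcripts)
pl <- pileup_tags(deg_tags, transcripts)
calls <- call_targets(sites, pl)
write.table(calls, file.path("results", "target_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

valid <- calls[calls$valid, ]
cat(sprintf("%d candidate sites, %d valid targets (%d dominant-peak)\n",
            nrow(calls), nrow(valid),
            sum(valid$category == "dominant-peak")))
if (nrow(valid)) {
  tp <- tplot_table(pl, valid$transcript_id[1])
  write.table(tp, file.path("results", "tplot_example.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
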