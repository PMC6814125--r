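#!/usr/bin/env Rscript
# Step 2: clean the raw small-RNA library (quality filter, adapter trim,
# unique-tag collapse) and the degradome library; write tag tables.

library(rootmir)

sim <- file.path("results", "sim")
adapter <- "CTGGAGTTCAGACGTGTGCTCTTCCGATCT"

reads <- read_fastq(file.path(sim, "srna_WW_R1.fastq"))
tags <- preprocess_srna(reads, adapter)
write.table(tags, file.path("results", "srna_tags.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

deg_reads <- read_fastq(file.path(sim, "degradome.fastq"))
deg_tags <- preprocess_degradome(deg_reads)
write.table(deg_tags, file.path("results", "degradome_tags.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("sRNA: %d raw reads -> %d unique tags (%d read counts)\n",
            nrow(reads), nrow(tags), sum(tags$count)))
cat(sprintf("degradome: %d raw reads -> %d unique 20-nt tags\n",
            nrow(deg_reads), nrow(deg_tags)))
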