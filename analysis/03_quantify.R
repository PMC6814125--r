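#!/usr/bin/env Rscript
# Step 3: assign tags to canonical miRNAs / isomiR classes, normalize the
# simulated count matrix to RPTM and apply the retention filter.

library(rootmir)

sim <- file.path("results", "sim")
reference <- read.delim(file.path(sim, "reference.tsv"))
tags <- read.delim(file.path("results", "srna_tags.tsv"))

assign <- match_tags(tags, reference)
write.table(assign, file.path("results", "tag_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cls <- tapply(assign$count, assign$class, sum)
cat("read counts by class:\n"); print(cls)

counts <- as.matrix(read.delim(file.path(sim, "counts.tsv"), row.names = 1,
                               check.names = FALSE))
libs <- read.delim(file.path(sim, "libraries.tsv"))
rptm <- rptm_normalize(counts, colSums(counts))
kept <- retention_filter(rptm, libs$group)
write.table(data.frame(mirna_id = kept),
            file.path("results", "retained_mirnas.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("retention filter: %d of %d miRNAs kept\n", length(kept),
            nrow(rptm)))
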