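#!/usr/bin/env Rscript
# Step 1: generate the full synthetic dataset (reference, transcripts,
# small-RNA FASTQ, degradome, count matrix, qPCR Ct table) under results/sim.

library(rootmir)

seed <- 1L
cfg <- sim_config(seed = seed)
out <- file.path("results", "sim")
simulate_dataset(cfg, out, srna_depth = 1e5)
cat("simulated dataset written to", out, "\n")
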