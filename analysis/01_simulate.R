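#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the data the downstream stages consume: a two-chromosome genome
# pair, a reference annotation (protein-coding / lncRNA / pseudogene loci),
# capture long-read candidate models with planted violation and novelty
# classes, short-read junction support with planted weak introns, evidence
# tracks (CAGE, TSS predictions, cCREs, TF peaks, GWAS hits, small RNAs,
# capture targets), a per-base conservation track, and chain alignments
# with planted 1:1 / 1:2 / lost gene fates. Ground truth is written next
# to the data so every later stage can be scored.

library(lncforge)

seed <- 20251001L %% 100000L
cfg <- sim_config(seed = seed)
bundle <- simulate_bundle(cfg)

dir.create("results", showWarnings = FALSE)
write_bundle(bundle, "results/sim")

message(sprintf("genome A: %s", paste(names(bundle$chrom_sizes_a),
                                      bundle$chrom_sizes_a, collapse = ", ")))
message(sprintf("reference A: %d genes / %d transcripts",
                n_genes(bundle$reference_a),
                n_transcripts(bundle$reference_a)))
message(sprintf("candidates: %d models (%d with planted filter violations)",
                n_transcripts(bundle$candidates),
                sum(bundle$truth$models$filter_violation != "none")))
message("bundle written to results/sim/")
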