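#!/usr/bin/env Rscript
# Stage 2: collapse candidate models by intron chain (termini ignored),
# classify their novelty against the reference, and summarize cross-sample
# sharing and targeted-region yield. Reads the stage-1 files from disk so
# the standard formats are exercised end to end.

library(lncforge)

sizes <- read_chrom_sizes("results/sim/genome_a.sizes")
reference <- read_gtf("results/sim/reference_a.gtf", chrom_sizes = sizes)
candidates <- read_gtf("results/sim/candidates.gtf", chrom_sizes = sizes)
samples <- read.table("results/sim/candidate_samples.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
meta <- read.table("results/sim/sample_meta.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
targets <- read_track("results/sim/targets.bed", "bed")

merged <- merge_models(candidates, samples, meta)
novelty <- classify_novelty(candidates, reference)
sharing <- sample_sharing(merged)
yield <- target_yield(targets, candidates)

write_gtf(merged$annotation, "results/merged.gtf")
write.table(novelty, "results/novelty.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sharing$summary, "results/sample_sharing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(yield$per_class, "results/target_yield.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d candidates -> %d merged models",
                n_transcripts(candidates), n_transcripts(merged$annotation)))
message(sprintf("novelty: %s",
                paste(names(table(novelty$category)), table(novelty$category),
                      sep = "=", collapse = ", ")))
message(sprintf("detected in exactly one sample: %.0f%%",
                100 * sharing$summary$frac_unique_sample))
message(sprintf("targeted regions detected: %.0f%%", 100 * yield$fraction))
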