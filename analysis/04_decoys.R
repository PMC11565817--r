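#!/usr/bin/env Rscript
# Stage 4: build decoy transcript models -- real exon/intron structures
# relocated into unannotated intergenic space (>= 1 kb from any locus).
# Decoys are the background baseline for every downstream comparison.

library(lncforge)

sizes <- read_chrom_sizes("results/sim/genome_a.sizes")
reference <- read_gtf("results/sim/reference_a.gtf", chrom_sizes = sizes)

decoys <- generate_decoys(reference, sizes,
                          decoy_config(n_decoys = 500L, seed = 7L,
                                       buffer = 1000L))
qc <- decoy_qc(decoys, reference)

write_gtf(decoys, "results/decoys.gtf")
write.table(data.frame(metric = names(qc), value = unlist(lapply(qc, format))),
            "results/decoy_qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("%d decoys placed; overlap violations: %d",
                n_transcripts(decoys), qc$n_overlap_violations))
message(sprintf("structure preserved (exon count / exonic length): %s / %s",
                qc$exon_count_match, qc$exonic_length_match))
message(sprintf("exonic-length KS distance to annotation: %.3f",
                qc$length_ks_stat))
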