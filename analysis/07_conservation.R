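#!/usr/bin/env Rscript
# Stage 7: per-transcript conservation. Mean per-base scores over exonic
# positions and over 2 bp splice-site windows, classified against the
# default neutral band (-1, 1); decoy exon means additionally calibrate an
# empirical band as a cross-check of the default.

library(lncforge)

sizes <- read_chrom_sizes("results/sim/genome_a.sizes")
reference <- read_gtf("results/sim/reference_a.gtf", chrom_sizes = sizes)
accepted <- read_gtf("results/accepted.gtf", chrom_sizes = sizes)
decoys <- read_gtf("results/decoys.gtf", chrom_sizes = sizes)
track <- read_track("results/sim/conservation.bedGraph", "bedgraph")

sets <- list(novel = accepted,
             lncRNA = subset_biotype(reference, "lncRNA"),
             protein_coding = subset_biotype(reference, "protein_coding"),
             decoy = decoys)
summ <- conservation_summary(sets, track)

write.table(summ$fractions, "results/conservation_fractions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
for (nm in names(summ$histograms))
  write.table(summ$histograms[[nm]],
              sprintf("results/conservation_hist_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)

band <- calibrate_band(summ$scores$decoy$exon_mean)
message(paste(capture.output(print(summ$fractions, digits = 3)),
              collapse = "\n"))
message(sprintf("decoy-calibrated neutral band: (%.3f, %.3f)",
                band$lower, band$upper))
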