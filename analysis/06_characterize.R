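#!/usr/bin/env Rscript
# Stage 6: evaluate four transcript sets -- accepted novel models,
# reference lncRNAs, protein-coding genes, and decoys -- against the
# evidence tracks: TSS support (CAGE and TSS predictions, +/- 50 bp), polyA
# motifs (10-50 bp upstream of the 3' end), cCRE support (< 2 kb center
# distance) and reclassification (200 bp / 2 kb), TF peak coverage
# profiles (500 bp windows over +/- 5 kb), GWAS densities (per 100 kb) and
# the +/- 15 kb meta-profile, and small-RNA host assignment.

library(lncforge)

sizes <- read_chrom_sizes("results/sim/genome_a.sizes")
reference <- read_gtf("results/sim/reference_a.gtf", chrom_sizes = sizes)
accepted <- read_gtf("results/accepted.gtf", chrom_sizes = sizes)
decoys <- read_gtf("results/decoys.gtf", chrom_sizes = sizes)
genome <- read_fasta("results/sim/genome_a.fa")
cage <- read_track("results/sim/cage.bed", "bed")
procap <- read_track("results/sim/procap.bed", "bed")
ccres <- read_track("results/sim/ccres.bed", "bed")
gwas <- read_track("results/sim/gwas.bed", "bed")
smallrna <- read_track("results/sim/smallrna.bed", "bed")
tf_files <- list.files("results/sim", pattern = "^tf_.*\\.bed$",
                       full.names = TRUE)
tf_peaks <- setNames(lapply(tf_files, read_track, kind = "bed"),
                     sub("^tf_(.*)\\.bed$", "\\1", basename(tf_files)))

sets <- list(novel = accepted,
             lncRNA = subset_biotype(reference, "lncRNA"),
             protein_coding = subset_biotype(reference, "protein_coding"),
             decoy = decoys)
evidence <- list(tss_tracks = list(cage = cage, procap = procap),
                 ccres = ccres, tf_peaks = tf_peaks, gwas = gwas,
                 genome = genome, chrom_sizes = sizes)

tab <- compare_sets(sets, evidence)
write.table(tab, "results/characterization.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(paste(capture.output(print(tab, digits = 3)), collapse = "\n"))

# cCRE reclassification against the enhanced TSS collection
enhanced <- extract_tss(lnc_annotation(rbind(
  lncforge:::as_exon_df(reference), lncforge:::as_exon_df(accepted)),
  chrom_sizes = sizes))
rc <- reclassify_ccres(ccres, enhanced)
write.table(rc$transitions, "results/ccre_transitions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rc$class_fractions, "results/ccre_class_fractions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
moved <- rc$transitions[rc$transitions$from != rc$transitions$to, ]
message(sprintf("cCREs reclassified: %s",
                paste(sprintf("%s->%s:%d", moved$from, moved$to, moved$count),
                      collapse = ", ")))

# GWAS profile along accepted gene bodies
prof <- gwas_profile(accepted, gwas)
write.table(prof, "results/gwas_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# small-RNA hosting within reference + accepted transcripts
hosts_ann <- lnc_annotation(rbind(lncforge:::as_exon_df(reference),
                                  lncforge:::as_exon_df(accepted)),
                            chrom_sizes = sizes)
hosts <- smallrna_hosts(smallrna, hosts_ann)
write.table(hosts$table, "results/smallrna_hosts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("small RNAs hosted: %.0f%%", 100 * hosts$fraction_hosted))
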