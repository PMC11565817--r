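#!/usr/bin/env Rscript
# Stage 5: exon-synteny reciprocal orthology of the lncRNA genes between
# the two simulated genomes, through the chain alignments in both
# directions, plus a lookup of a (synthetic) disease-associated gene list.

library(lncforge)

sizes_a <- read_chrom_sizes("results/sim/genome_a.sizes")
sizes_b <- read_chrom_sizes("results/sim/genome_b.sizes")
ref_a <- read_gtf("results/sim/reference_a.gtf", chrom_sizes = sizes_a)
ref_b <- read_gtf("results/sim/reference_b.gtf", chrom_sizes = sizes_b)
chains_ab <- read_chain("results/sim/chains_ab.chain")
chains_ba <- read_chain("results/sim/chains_ba.chain")
truth <- read.table("results/sim/truth_orthologs.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE, na.strings = NULL)
truth$partners[is.na(truth$partners)] <- ""

lnc_a <- subset_biotype(ref_a, "lncRNA")
lnc_b <- subset_biotype(ref_b, "lncRNA")
res <- reciprocal_orthology(lnc_a, lnc_b, chains_ab, chains_ba)

write.table(res$calls, "results/orthology_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$edges, "results/orthology_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

calls_a <- res$calls[res$calls$genome == "A", ]
tr <- merge(truth, calls_a, by.x = "gene_a", by.y = "gene")
message(sprintf("orthology classes (genome A): %s",
                paste(names(table(calls_a$class)), table(calls_a$class),
                      sep = "=", collapse = ", ")))
message(sprintf("planted fate recovered for %d/%d genes",
                sum(tr$class.x == tr$class.y), nrow(tr)))

# synthetic stand-in for a clinically-derived gene list: every fourth
# lncRNA gene
disease <- data.frame(gene_id = lnc_a$genes$gene_id[
  seq(1, nrow(lnc_a$genes), by = 4)])
lk <- disease_ortholog_lookup(res, disease)
write.table(lk$table, "results/disease_orthologs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("disease-list genes with a mouse-side ortholog: %d/%d (%.0f%%)",
                lk$n_with_ortholog, lk$n_listed,
                100 * lk$fraction_with_ortholog))
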