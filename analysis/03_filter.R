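#!/usr/bin/env Rscript
# Stage 3: acceptance filtering of candidate models against the reference.
# Three independent predicates (antisense to protein-coding exons,
# containment in pseudogene bounds, any intron below 50 supporting reads)
# plus a non-rejecting flag for models that would merge distinct lncRNA
# genes. The per-model report is scored against the planted truth.

library(lncforge)

sizes <- read_chrom_sizes("results/sim/genome_a.sizes")
reference <- read_gtf("results/sim/reference_a.gtf", chrom_sizes = sizes)
candidates <- read_gtf("results/sim/candidates.gtf", chrom_sizes = sizes)
junctions <- read_junction_support("results/sim/junctions.tsv")
truth <- read.table("results/sim/truth_models.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

res <- run_tagene(candidates, reference, junctions,
                  filter_config(min_junction_reads = 50L))

write_gtf(res$accepted, "results/accepted.gtf")
write.table(res$report, "results/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ev <- truth_eval(
  data.frame(id = res$report$model_id,
             class = ifelse(res$report$reasons == "", "none",
                            res$report$reasons)),
  data.frame(id = truth$model_id, class = truth$filter_violation))
write.table(ev, "results/filter_truth_eval.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("accepted %d of %d models",
                n_transcripts(res$accepted), n_transcripts(candidates)))
message(sprintf("rejection reasons: %s",
                paste(capture.output(print(ev[, c("class", "precision",
                                                  "recall")])),
                      collapse = "\n")))
if (nrow(res$merge_flags))
  message(sprintf("%d model(s) flagged as potential locus merges",
                  nrow(res$merge_flags)))
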