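# One-command end-to-end run over a synthetic bundle: simulate -> merge ->
# novelty -> filter -> decoys -> orthology -> characterize -> conserve.
# Every number it reports is recomputed by the stage functions; the writer
# emits the summary tables as TSVs.

#' Restrict an annotation to one gene biotype
#' @param ann An [lnc_annotation()].
#' @param biotype Biotype label to keep.
#' @return An [lnc_annotation()] of matching genes' transcripts.
#' @export
subset_biotype <- function(ann, biotype) {
  keep <- ann$transcripts$transcript_id[ann$transcripts$biotype == biotype]
  ann_subset(ann, keep)
}

#' Run the full pipeline on a synthetic bundle
#'
#' Simulates a bundle (unless one is supplied), then runs every stage:
#' intron-chain merging and sample sharing, novelty classification,
#' acceptance filtering with per-model reasons, decoy generation and QC,
#' reciprocal exon-synteny orthology of the lncRNA genes, evidence-track
#' characterization of novel/lncRNA/protein-coding/decoy sets, and
#' conservation classification against the default neutral band.
#'
#' @param seed Integer seed driving the simulation and decoy placement.
#' @param out_dir Optional directory; when given, summary tables, the
#'   bundle and a run manifest are written there.
#' @param cfg Optional [sim_config()] (defaults to `sim_config(seed)`).
#' @param bundle Optional pre-built `sim_bundle` (overrides `cfg`).
#' @param n_decoys Decoy transcripts to generate.
#' @return A list of class `demo_result` with elements `bundle`, `merged`,
#'   `novelty`, `sharing`, `yield`, `tagene`, `decoys`, `decoy_qc`,
#'   `orthology`, `characterization`, `reclassification`, `gwas`,
#'   `small_rna`, `conservation`, `calibrated_band`.
#' @export
run_demo <- function(seed, out_dir = NULL, cfg = NULL, bundle = NULL,
                     n_decoys = 300L) {
  if (is.null(bundle)) {
    if (is.null(cfg)) cfg <- sim_config(seed)
    bundle <- simulate_bundle(cfg)
  }

  merged <- merge_models(bundle$candidates, bundle$candidate_samples,
                         bundle$sample_meta)
  novelty <- classify_novelty(bundle$candidates, bundle$reference_a)
  sharing <- sample_sharing(merged)
  yield <- target_yield(bundle$targets, bundle$candidates)
  tagene <- run_tagene(bundle$candidates, bundle$reference_a,
                       bundle$junctions)

  decoys <- generate_decoys(bundle$reference_a, bundle$chrom_sizes_a,
                            decoy_config(n_decoys, seed = seed + 1L))
  dqc <- decoy_qc(decoys, bundle$reference_a)

  lnc_a <- subset_biotype(bundle$reference_a, "lncRNA")
  lnc_b <- subset_biotype(bundle$reference_b, "lncRNA")
  orth <- reciprocal_orthology(lnc_a, lnc_b, bundle$chains_ab,
                               bundle$chains_ba)

  sets <- list(novel = tagene$accepted,
               lncRNA = lnc_a,
               protein_coding = subset_biotype(bundle$reference_a,
                                               "protein_coding"),
               decoy = decoys)
  evidence <- list(tss_tracks = list(cage = bundle$cage,
                                     procap = bundle$procap),
                   ccres = bundle$ccres, tf_peaks = bundle$tf_peaks,
                   gwas = bundle$gwas, genome = bundle$genome_a,
                   chrom_sizes = bundle$chrom_sizes_a)
  characterization <- compare_sets(sets, evidence)

  enhanced_tss <- extract_tss(lnc_annotation(rbind(
    as_exon_df(bundle$reference_a), as_exon_df(tagene$accepted)),
    chrom_sizes = bundle$chrom_sizes_a))
  reclass <- reclassify_ccres(bundle$ccres, enhanced_tss)

  gwas <- list(
    body = gwas_density(tagene$accepted, bundle$gwas, "gene_body"),
    exons = gwas_density(tagene$accepted, bundle$gwas, "exons"),
    complement = gwas_density(tagene$accepted, bundle$gwas, "complement",
                              chrom_sizes = bundle$chrom_sizes_a),
    profile = gwas_profile(tagene$accepted, bundle$gwas))

  hosts_ann <- lnc_annotation(rbind(as_exon_df(bundle$reference_a),
                                    as_exon_df(tagene$accepted)),
                              chrom_sizes = bundle$chrom_sizes_a)
  small_rna <- smallrna_hosts(bundle$small_rnas, hosts_ann)

  conservation <- conservation_summary(sets, bundle$conservation)
  decoy_scores <- conservation$scores$decoy$exon_mean
  calibrated <- calibrate_band(decoy_scores)

  result <- structure(list(
    bundle = bundle, merged = merged, novelty = novelty, sharing = sharing,
    yield = yield, tagene = tagene, decoys = decoys, decoy_qc = dqc,
    orthology = orth, characterization = characterization,
    reclassification = reclass, gwas = gwas, small_rna = small_rna,
    conservation = conservation, calibrated_band = calibrated,
    seed = seed), class = "demo_result")

  if (!is.null(out_dir)) write_demo(result, out_dir)
  result
}

# exon table of an annotation (inverse of the lnc_annotation constructor)
as_exon_df <- function(ann) {
  gr <- ann$exons
  bt <- setNames(ann$transcripts$biotype, ann$transcripts$transcript_id)
  tid <- S4Vectors::mcols(gr)$transcript_id
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             transcript_id = tid,
             gene_id = S4Vectors::mcols(gr)$gene_id,
             biotype = unname(bt[tid]),
             stringsAsFactors = FALSE)
}

write_demo <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  tsv <- function(df, f) write.table(df, p(f), sep = "\t", quote = FALSE,
                                     row.names = FALSE)
  write_bundle(result$bundle, file.path(out_dir, "bundle"))
  write_gtf(result$merged$annotation, p("merged.gtf"))
  tsv(result$novelty, "novelty.tsv")
  tsv(result$sharing$summary, "sample_sharing.tsv")
  tsv(result$yield$per_class, "target_yield.tsv")
  tsv(result$tagene$report, "filter_report.tsv")
  write_gtf(result$tagene$accepted, p("accepted.gtf"))
  write_gtf(result$decoys, p("decoys.gtf"))
  tsv(result$orthology$calls, "orthology_calls.tsv")
  tsv(result$orthology$edges, "orthology_edges.tsv")
  tsv(result$characterization, "characterization.tsv")
  tsv(result$reclassification$transitions, "ccre_transitions.tsv")
  tsv(result$reclassification$class_fractions, "ccre_class_fractions.tsv")
  tsv(result$gwas$profile, "gwas_profile.tsv")
  tsv(result$small_rna$table, "smallrna_hosts.tsv")
  tsv(result$conservation$fractions, "conservation_fractions.tsv")
  manifest <- data.frame(
    key = c("seed", "n_candidates", "n_decoys", "package_version"),
    value = c(result$seed, n_transcripts(result$bundle$candidates),
              n_transcripts(result$decoys),
              as.character(utils::packageVersion("lncforge"))))
  tsv(manifest, "manifest.tsv")
  invisible(out_dir)
}

#' @export
print.demo_result <- function(x, ...) {
  cat("lncforge demo result (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  candidates: %d -> merged: %d -> accepted: %d\n",
              n_transcripts(x$bundle$candidates),
              n_transcripts(x$merged$annotation),
              n_transcripts(x$tagene$accepted)))
  cat(sprintf("  unique-sample fraction: %.2f; target yield: %.2f\n",
              x$sharing$summary$frac_unique_sample, x$yield$fraction))
  one2one <- sum(x$orthology$calls$class == "one_to_one" &
                   x$orthology$calls$genome == "A")
  cat(sprintf("  lncRNA orthology: %d one-to-one (of %d genome-A genes)\n",
              one2one, sum(x$orthology$calls$genome == "A")))
  cat(sprintf("  decoy overlap violations: %d\n",
              x$decoy_qc$n_overlap_violations))
  invisible(x)
}
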