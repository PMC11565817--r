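# Acceptance filtering of candidate models into the reference annotation.
# Three independent rejection predicates (antisense to protein-coding,
# contained in pseudogene bounds, weak splice-junction support) plus a
# non-rejecting locus-merge guard. Reasons accumulate; a model is accepted
# iff it triggers none of the enabled predicates.

#' Filter configuration for [run_tagene()]
#'
#' @param min_junction_reads Minimum short-read count per intron; a model is
#'   rejected if any of its introns is supported by fewer reads (strictly
#'   less). Default 50.
#' @param apply_antisense,apply_pseudogene,apply_junction Enable/disable the
#'   individual predicates.
#' @param flag_merges Report models bridging two or more distinct
#'   same-strand reference lncRNA genes.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_junction_reads = 50L, apply_antisense = TRUE,
                          apply_pseudogene = TRUE, apply_junction = TRUE,
                          flag_merges = TRUE) {
  if (min_junction_reads < 0)
    stop("min_junction_reads must be >= 0")
  structure(list(min_junction_reads = as.integer(min_junction_reads),
                 apply_antisense = apply_antisense,
                 apply_pseudogene = apply_pseudogene,
                 apply_junction = apply_junction,
                 flag_merges = flag_merges),
            class = "filter_config")
}

#' Models antisense to protein-coding genes
#'
#' A model violates iff >=1 bp of its exons overlaps exons of a
#' protein-coding reference gene on the opposite strand. Span-level
#' (intronic) antisense positioning is deliberately retained.
#'
#' @param models,reference [lnc_annotation()] objects; reference biotypes
#'   must be populated.
#' @return Character vector of violating model transcript ids.
#' @export
filter_antisense_pc <- function(models, reference) {
  pc_genes <- reference$genes$gene_id[reference$genes$biotype == "protein_coding"]
  rex <- reference$exons[S4Vectors::mcols(reference$exons)$gene_id %in% pc_genes]
  if (!length(rex)) return(character(0))
  mex <- models$exons
  h <- GenomicRanges::findOverlaps(mex, rex, ignore.strand = TRUE)
  opp <- as.character(GenomicRanges::strand(mex))[S4Vectors::queryHits(h)] !=
    as.character(GenomicRanges::strand(rex))[S4Vectors::subjectHits(h)]
  sort(unique(S4Vectors::mcols(mex)$transcript_id[S4Vectors::queryHits(h)[opp]]))
}

#' Models contained in pseudogene genomic bounds
#'
#' Violation is strand-agnostic span containment: the model's full span must
#' lie inside some pseudogene locus span.
#'
#' @inheritParams filter_antisense_pc
#' @return Character vector of violating model transcript ids.
#' @export
filter_pseudogene_contained <- function(models, reference) {
  ps <- gene_spans(reference)
  ps <- ps[S4Vectors::mcols(ps)$biotype == "pseudogene"]
  if (!length(ps)) return(character(0))
  spans <- tx_spans(models)
  h <- GenomicRanges::findOverlaps(spans, ps, type = "within",
                                   ignore.strand = TRUE)
  sort(unique(names(spans)[S4Vectors::queryHits(h)]))
}

#' Models with weakly supported splice junctions
#'
#' A model violates iff any of its introns has a short-read support count
#' strictly below `min_reads`. Monoexonic models pass vacuously.
#'
#' @param models An [lnc_annotation()].
#' @param support A `junction_support` table ([read_junction_support()]).
#' @param min_reads Threshold; introns with `count < min_reads` reject.
#' @return Character vector of violating model transcript ids.
#' @export
filter_junction_support <- function(models, support, min_reads = 50L) {
  intr <- introns_of(models)
  if (!nrow(intr)) return(character(0))
  cnt <- junction_count(support, junction_key(intr$chrom, intr$strand,
                                              intr$intron_start, intr$intron_end))
  sort(unique(intr$transcript_id[cnt < min_reads]))
}

#' Flag models that would merge distinct lncRNA genes
#'
#' A model is flagged when its exons overlap exons of two or more distinct
#' same-strand reference lncRNA genes. Flagged models are reported for
#' curation, never auto-rejected.
#'
#' @inheritParams filter_antisense_pc
#' @return `data.frame` with `model_id` and comma-joined `merge_genes`.
#' @export
flag_locus_merges <- function(models, reference) {
  lnc <- reference$genes$gene_id[reference$genes$biotype == "lncRNA"]
  rex <- reference$exons[S4Vectors::mcols(reference$exons)$gene_id %in% lnc]
  empty <- data.frame(model_id = character(), merge_genes = character(),
                      stringsAsFactors = FALSE)
  if (!length(rex)) return(empty)
  mex <- models$exons
  h <- GenomicRanges::findOverlaps(mex, rex) # strand-matched
  if (!length(h)) return(empty)
  pairs <- unique(data.frame(
    model_id = S4Vectors::mcols(mex)$transcript_id[S4Vectors::queryHits(h)],
    gene = S4Vectors::mcols(rex)$gene_id[S4Vectors::subjectHits(h)],
    stringsAsFactors = FALSE))
  ng <- table(pairs$model_id)
  flagged <- names(ng)[ng >= 2L]
  if (!length(flagged)) return(empty)
  data.frame(
    model_id = flagged,
    merge_genes = vapply(flagged, function(id)
      paste(sort(pairs$gene[pairs$model_id == id]), collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full acceptance filter
#'
#' Applies the antisense, pseudogene-containment and junction-support
#' predicates (in that order, though the predicates are independent and the
#' result is order-invariant), accumulating every applicable rejection
#' reason per model, and computes locus-merge flags.
#'
#' @param models,reference [lnc_annotation()] objects.
#' @param support A `junction_support` table (may be `NULL` when the
#'   junction predicate is disabled).
#' @param config A [filter_config()].
#' @return A list of class `tagene_result`: `accepted` (an
#'   [lnc_annotation()] of models with no rejection reason), `report`
#'   (`model_id`, `decision`, comma-joined `reasons`, `merge_genes`), and
#'   `merge_flags`.
#' @export
run_tagene <- function(models, reference, support = NULL,
                       config = filter_config()) {
  stopifnot(is(config, "filter_config"))
  ids <- models$transcripts$transcript_id
  reasons <- setNames(vector("list", length(ids)), ids)
  add_reason <- function(viol, tag) {
    for (id in viol) reasons[[id]] <<- c(reasons[[id]], tag)
    reasons
  }
  if (config$apply_antisense)
    reasons <- add_reason(filter_antisense_pc(models, reference), "antisense_pc")
  if (config$apply_pseudogene)
    reasons <- add_reason(filter_pseudogene_contained(models, reference),
                          "pseudogene_contained")
  if (config$apply_junction) {
    if (is.null(support))
      stop("junction filter enabled but no support table given")
    reasons <- add_reason(
      filter_junction_support(models, support, config$min_junction_reads),
      "low_junction_support")
  }
  merge_flags <- if (config$flag_merges) flag_locus_merges(models, reference)
    else data.frame(model_id = character(), merge_genes = character())

  reason_str <- vapply(reasons, function(r)
    paste(unique(r), collapse = ","), "")
  decision <- ifelse(nzchar(reason_str), "rejected", "accepted")
  report <- data.frame(
    model_id = ids, decision = decision, reasons = reason_str,
    merge_genes = ifelse(ids %in% merge_flags$model_id,
                         merge_flags$merge_genes[match(ids, merge_flags$model_id)],
                         ""),
    stringsAsFactors = FALSE)
  accepted <- ann_subset(models, ids[decision == "accepted"])
  structure(list(accepted = accepted, report = report,
                 merge_flags = merge_flags),
            class = "tagene_result")
}
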