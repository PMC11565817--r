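# Intron-chain collapsing and novelty calling. The identity key of a
# spliced transcript is its ordered (donor, acceptor) list -- termini are
# ignored, mirroring how capture long-read models are deduplicated before
# annotation. Monoexonic models have an empty chain and fall back to
# reciprocal span overlap.

#' Intron-chain keys for every transcript
#'
#' Two models with identical internal splice junctions but different termini
#' share a key. Monoexonic transcripts get the key `"<chrom>|<strand>|mono"`
#' which is deliberately not unique: their grouping is resolved by span
#' overlap in [merge_models()].
#'
#' @param ann An [lnc_annotation()].
#' @return Named character vector, one key per transcript.
#' @export
intron_chain_keys <- function(ann) {
  intr <- introns_of(ann)
  keys <- setNames(sprintf("%s|%s|mono", ann$transcripts$chrom,
                           ann$transcripts$strand),
                   ann$transcripts$transcript_id)
  if (nrow(intr)) {
    intr <- intr[order(intr$transcript_id, intr$intron_start), , drop = FALSE]
    chain_str <- tapply(sprintf("%d-%d", intr$intron_start, intr$intron_end),
                        intr$transcript_id, paste, collapse = ",")
    tx_ids <- names(chain_str)
    tx <- ann$transcripts[match(tx_ids, ann$transcripts$transcript_id), ]
    keys[tx_ids] <- sprintf("%s|%s|%s", tx$chrom, tx$strand, chain_str)
  }
  keys
}

# connected components of an undirected pair list over 1..n (union-find)
components_of_pairs <- function(n, a, b) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

# group monoexonic spans on one chrom/strand by >=50% reciprocal overlap
mono_groups <- function(spans, min_reciprocal = 0.5) {
  hits <- GenomicRanges::findOverlaps(spans, spans)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- q < s
  q <- q[keep]; s <- s[keep]
  if (length(q)) {
    ov <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(spans)[q], GenomicRanges::ranges(spans)[s]))
    wq <- GenomicRanges::width(spans)[q]
    ws <- GenomicRanges::width(spans)[s]
    keep2 <- ov >= min_reciprocal * wq & ov >= min_reciprocal * ws
    q <- q[keep2]; s <- s[keep2]
  }
  components_of_pairs(length(spans), q, s)
}

#' Collapse transcript models by intron chain across samples
#'
#' One merged model is produced per intron-chain key; representative termini
#' are the extremal (5'-most start, 3'-most end) over members, so the merged
#' model preserves the full evidence span. Monoexonic models merge when on
#' the same strand with at least `min_reciprocal` reciprocal span overlap.
#' A sample matrix records per-sample detection of each merged model.
#'
#' @param models An [lnc_annotation()] of candidate transcript models.
#' @param samples A `data.frame` mapping `transcript_id` to `sample_id`
#'   (a model observed in several samples has several rows).
#' @param sample_meta Optional `data.frame` with columns `sample_id`,
#'   `tissue`, `stage` (`adult`/`embryo`), `capture` (`pre`/`post`).
#' @param min_reciprocal Reciprocal-overlap fraction for monoexonic merging.
#' @return A list of class `merged_models`: `annotation` (merged
#'   [lnc_annotation()], ids `M<k>`), `members` (merged id to member
#'   transcript id provenance), `sample_matrix` (merged id x sample
#'   detections) and `sample_meta`.
#' @export
merge_models <- function(models, samples = NULL, sample_meta = NULL,
                         min_reciprocal = 0.5) {
  tx <- models$transcripts
  keys <- intron_chain_keys(models)
  grp <- match(keys, unique(keys))
  mono <- tx$n_exons == 1L
  if (any(mono)) {
    # refine every mono pseudo-key by reciprocal span overlap
    for (k in unique(keys[mono])) {
      idx <- which(keys == k)
      spans <- GenomicRanges::GRanges(tx$chrom[idx],
                                      IRanges::IRanges(tx$start[idx], tx$end[idx]))
      comp <- mono_groups(spans, min_reciprocal)
      grp[idx] <- max(grp) + comp
    }
    grp <- match(grp, unique(grp))
  }

  intr <- introns_of(models)
  exon_rows <- list()
  members <- list()
  ord_tbl <- data.frame(grp = grp, chrom = tx$chrom, start = tx$start)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(tx)), grp), function(i)
    data.frame(grp = grp[i[1]], chrom = tx$chrom[i[1]],
               start = min(tx$start[i]), end = max(tx$end[i]),
               strand = tx$strand[i[1]], biotype = tx$biotype[i[1]],
               rep_tx = tx$transcript_id[i[1]],
               member_ids = I(list(sort(tx$transcript_id[i]))))))
  agg <- agg[order(agg$chrom, agg$start, agg$end), , drop = FALSE]
  agg$merged_id <- sprintf("M%05d", seq_len(nrow(agg)))

  for (i in seq_len(nrow(agg))) {
    ji <- intr[intr$transcript_id == agg$rep_tx[i], , drop = FALSE]
    ji <- ji[order(ji$intron_start), , drop = FALSE]
    starts <- c(agg$start[i], ji$intron_end + 1L)
    ends <- c(ji$intron_start - 1L, agg$end[i])
    exon_rows[[i]] <- data.frame(
      chrom = agg$chrom[i], start = starts, end = ends,
      strand = agg$strand[i], transcript_id = agg$merged_id[i],
      gene_id = agg$merged_id[i], biotype = agg$biotype[i],
      stringsAsFactors = FALSE)
    members[[i]] <- data.frame(merged_id = agg$merged_id[i],
                               member_id = unlist(agg$member_ids[i]),
                               stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, members)
  merged_ann <- lnc_annotation(do.call(rbind, exon_rows))

  sample_matrix <- NULL
  if (!is.null(samples)) {
    sm <- merge(members, samples, by.x = "member_id", by.y = "transcript_id")
    sample_matrix <- unique(sm[, c("merged_id", "sample_id")])
    sample_matrix <- sample_matrix[order(sample_matrix$merged_id,
                                         sample_matrix$sample_id), ]
    rownames(sample_matrix) <- NULL
  }
  structure(list(annotation = merged_ann, members = members,
                 sample_matrix = sample_matrix, sample_meta = sample_meta),
            class = "merged_models")
}

#' Classify novelty of transcript models against a reference
#'
#' Categories follow a fixed precedence: `known` (intron chain matches a
#' reference transcript; monoexonic models are known when they reciprocally
#' overlap a same-strand monoexonic reference transcript by at least 50%),
#' else `novel_transcript_known_gene` (>=1 bp same-strand exonic overlap),
#' else `intronic_overlap` (contained in a same-strand reference gene span
#' with no exonic overlap), else `antisense_overlap` (exonic overlap with an
#' opposite-strand gene's exons), else `novel_gene_intergenic`.
#'
#' @param models,reference [lnc_annotation()] objects.
#' @return A `data.frame`: `model_id`, `category`, `matched_ids`
#'   (comma-joined reference transcript/gene ids, `""` when none).
#' @export
classify_novelty <- function(models, reference) {
  mtx <- models$transcripts
  mkeys <- intron_chain_keys(models)
  rkeys <- intron_chain_keys(reference)
  rtx <- reference$transcripts
  spliced_ref <- setNames(rtx$transcript_id, rkeys)[rtx$n_exons > 1L]

  category <- rep("novel_gene_intergenic", nrow(mtx))
  matched <- rep("", nrow(mtx))

  ## known: spliced chain match
  spliced <- mtx$n_exons > 1L
  hit <- mkeys %in% names(spliced_ref)
  known <- spliced & hit
  matched[known] <- unname(spliced_ref[mkeys[known]])
  ## known: monoexonic reciprocal overlap with mono reference transcript
  mono_ref <- tx_spans(reference)[rtx$n_exons == 1L]
  if (length(mono_ref) && any(!spliced)) {
    mono_idx <- which(!spliced)
    spans <- GenomicRanges::GRanges(mtx$chrom[mono_idx],
                                    IRanges::IRanges(mtx$start[mono_idx],
                                                     mtx$end[mono_idx]),
                                    strand = mtx$strand[mono_idx])
    h <- GenomicRanges::findOverlaps(spans, mono_ref)
    if (length(h)) {
      q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
      ov <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(spans)[q], GenomicRanges::ranges(mono_ref)[s]))
      ok <- ov >= 0.5 * GenomicRanges::width(spans)[q] &
        ov >= 0.5 * GenomicRanges::width(mono_ref)[s]
      for (k in which(ok)) {
        i <- mono_idx[q[k]]
        known[i] <- TRUE
        matched[i] <- names(mono_ref)[s[k]]
      }
    }
  }
  category[known] <- "known"

  mex <- models$exons
  mex_tx <- S4Vectors::mcols(mex)$transcript_id
  rex <- reference$exons
  rex_gene <- S4Vectors::mcols(rex)$gene_id

  ## exonic overlap on either strand, split into same/antisense pairs
  h <- GenomicRanges::findOverlaps(mex, rex, ignore.strand = TRUE)
  same <- as.character(GenomicRanges::strand(mex))[S4Vectors::queryHits(h)] ==
    as.character(GenomicRanges::strand(rex))[S4Vectors::subjectHits(h)]
  ss_pairs <- unique(data.frame(
    tx = mex_tx[S4Vectors::queryHits(h)[same]],
    gene = rex_gene[S4Vectors::subjectHits(h)[same]]))
  as_pairs <- unique(data.frame(
    tx = mex_tx[S4Vectors::queryHits(h)[!same]],
    gene = rex_gene[S4Vectors::subjectHits(h)[!same]]))

  idx_ss <- !known & mtx$transcript_id %in% ss_pairs$tx
  category[idx_ss] <- "novel_transcript_known_gene"
  matched[idx_ss] <- vapply(mtx$transcript_id[idx_ss], function(id)
    paste(sort(unique(ss_pairs$gene[ss_pairs$tx == id])), collapse = ","), "")

  ## intronic: contained in same-strand gene span, no exonic overlap
  remaining <- !known & !idx_ss
  if (any(remaining)) {
    spans <- GenomicRanges::GRanges(mtx$chrom, IRanges::IRanges(mtx$start, mtx$end),
                                    strand = mtx$strand)[remaining]
    gs <- gene_spans(reference)
    h2 <- GenomicRanges::findOverlaps(spans, gs, type = "within")
    if (length(h2)) {
      ridx <- which(remaining)
      for (k in seq_along(h2)) {
        i <- ridx[S4Vectors::queryHits(h2)[k]]
        if (category[i] == "intronic_overlap") {
          matched[i] <- paste(matched[i], names(gs)[S4Vectors::subjectHits(h2)[k]],
                              sep = ",")
        } else {
          category[i] <- "intronic_overlap"
          matched[i] <- names(gs)[S4Vectors::subjectHits(h2)[k]]
        }
      }
    }
  }

  ## antisense exonic overlap
  idx_as <- category == "novel_gene_intergenic" &
    mtx$transcript_id %in% as_pairs$tx
  category[idx_as] <- "antisense_overlap"
  matched[idx_as] <- vapply(mtx$transcript_id[idx_as], function(id)
    paste(sort(unique(as_pairs$gene[as_pairs$tx == id])), collapse = ","), "")

  data.frame(model_id = mtx$transcript_id, category = category,
             matched_ids = matched, stringsAsFactors = FALSE)
}

#' Cross-sample sharing of merged models
#'
#' @param merged A `merged_models` object (or a `data.frame` with columns
#'   `merged_id`, `sample_id`) whose sample metadata carries `stage` and
#'   `capture` per sample.
#' @param sample_meta Sample metadata; taken from `merged` when omitted.
#' @return A list: `per_model` (`merged_id`, `n_samples`, `stage_class` in
#'   adult/embryo/both, `capture_class` in pre/post/both) and `summary`
#'   (fractions detected in exactly one sample, adult-only, embryo-only,
#'   both stages, pre-capture-only, post-capture-only).
#' @export
sample_sharing <- function(merged, sample_meta = NULL) {
  sm <- if (is.data.frame(merged)) merged else merged$sample_matrix
  if (is.null(sample_meta) && !is.data.frame(merged))
    sample_meta <- merged$sample_meta
  stopifnot(!is.null(sm), nrow(sm) > 0)
  per <- data.frame(merged_id = unique(sm$merged_id))
  cnt <- table(sm$merged_id)
  per$n_samples <- as.integer(cnt[per$merged_id])
  per$stage_class <- NA_character_
  per$capture_class <- NA_character_
  if (!is.null(sample_meta)) {
    m <- merge(sm, sample_meta, by = "sample_id")
    cls <- function(v, both = "both") {
      u <- unique(v)
      if (length(u) == 1L) u else both
    }
    st <- tapply(m$stage, m$merged_id, cls)
    cp <- tapply(m$capture, m$merged_id, cls)
    per$stage_class <- unname(st[per$merged_id])
    per$capture_class <- unname(cp[per$merged_id])
  }
  n <- nrow(per)
  summary <- data.frame(
    n_models = n,
    frac_unique_sample = mean(per$n_samples == 1L),
    frac_adult_only = mean(per$stage_class == "adult"),
    frac_embryo_only = mean(per$stage_class == "embryo"),
    frac_both_stages = mean(per$stage_class == "both"),
    frac_pre_only = mean(per$capture_class == "pre"),
    frac_post_only = mean(per$capture_class == "post")
  )
  list(per_model = per, summary = summary)
}

#' Fraction of targeted regions detected by transcript models
#'
#' A target is detected iff at least one model exon overlaps it; overlap is
#' strand-matched for stranded targets and strand-agnostic otherwise.
#'
#' @param targets `GRanges` of targeted regions; an optional `label` column
#'   names the catalog of origin for the per-class table.
#' @param models An [lnc_annotation()].
#' @return A list: `fraction` (overall detected fraction), `per_class`
#'   (`class`, `n`, `n_detected`, `fraction`), `detected` (logical per
#'   target).
#' @export
target_yield <- function(targets, models) {
  ex <- models$exons
  stranded <- as.character(GenomicRanges::strand(targets)) %in% c("+", "-")
  det <- logical(length(targets))
  if (any(stranded))
    det[stranded] <- IRanges::overlapsAny(targets[stranded], ex,
                                                ignore.strand = FALSE)
  if (any(!stranded))
    det[!stranded] <- IRanges::overlapsAny(targets[!stranded], ex,
                                                 ignore.strand = TRUE)
  lab <- S4Vectors::mcols(targets)$label
  if (is.null(lab)) lab <- rep("all", length(targets))
  per_class <- do.call(rbind, lapply(split(seq_along(targets), lab), function(i)
    data.frame(class = lab[i[1]], n = length(i), n_detected = sum(det[i]),
               fraction = mean(det[i]))))
  rownames(per_class) <- NULL
  list(fraction = mean(det), per_class = per_class, detected = det)
}
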