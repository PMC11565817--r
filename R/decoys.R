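# Decoy transcript models: real exon/intron structures relocated into
# unannotated intergenic space, the non-genic background baseline used by
# every evaluation. Placement is uniform on the source chromosome with
# rejection of any position overlapping an annotated locus span +/- buffer.

#' Configuration for [generate_decoys()]
#'
#' @param n_decoys Number of decoy transcripts to produce (>= 1).
#' @param seed Integer RNG seed; placement is fully deterministic given the
#'   seed (integer draws only).
#' @param buffer Required distance (bp) from any annotated locus span.
#' @param max_attempts Placement attempts per decoy before erroring.
#' @return A list of class `decoy_config`.
#' @export
decoy_config <- function(n_decoys, seed, buffer = 1000L, max_attempts = 1000L) {
  stopifnot(n_decoys >= 1, buffer >= 0, max_attempts >= 1)
  structure(list(n_decoys = as.integer(n_decoys), seed = as.integer(seed),
                 buffer = as.integer(buffer),
                 max_attempts = as.integer(max_attempts)),
            class = "decoy_config")
}

#' Generate decoy transcript models
#'
#' Each decoy copies the exon/intron length sequence and strand of a
#' uniformly sampled source transcript and is placed at a uniformly sampled
#' position on the same chromosome; placements whose span intersects any
#' annotated locus span extended by `buffer` (or runs off the chromosome)
#' are rejected and resampled. Provenance records the source transcript.
#'
#' @param annotation Source [lnc_annotation()] (defines both the structure
#'   pool and the excluded genic space).
#' @param chrom_sizes Named integer vector of chromosome sizes.
#' @param config A [decoy_config()].
#' @return An [lnc_annotation()] of decoys (ids `D<k>`, biotype `other`),
#'   with a `sources` attribute (`data.frame`: `decoy_id`, `source_id`).
#' @export
generate_decoys <- function(annotation, chrom_sizes, config) {
  stopifnot(is(config, "decoy_config"))
  missing_chr <- setdiff(unique(annotation$genes$chrom), names(chrom_sizes))
  if (length(missing_chr))
    stop("chrom_sizes lacks: ", paste(missing_chr, collapse = ", "))
  excl <- GenomicRanges::reduce(
    GenomicRanges::resize(gene_spans(annotation),
                          GenomicRanges::width(gene_spans(annotation)) +
                            2L * config$buffer, fix = "center"),
    ignore.strand = TRUE)

  ex <- annotation$exons
  ex_tx <- S4Vectors::mcols(ex)$transcript_id
  tx <- annotation$transcripts
  set.seed(config$seed)
  src_idx <- sample.int(nrow(tx), config$n_decoys, replace = TRUE)

  rows <- vector("list", config$n_decoys)
  sources <- character(config$n_decoys)
  for (d in seq_len(config$n_decoys)) {
    ti <- tx[src_idx[d], ]
    e <- ex[ex_tx == ti$transcript_id]
    e <- e[order(GenomicRanges::start(e))]
    offs <- GenomicRanges::start(e) - ti$start       # exon offsets in span
    lens <- GenomicRanges::width(e)
    span_len <- ti$end - ti$start + 1L
    csize <- chrom_sizes[[ti$chrom]]
    placed <- FALSE
    for (a in seq_len(config$max_attempts)) {
      pos <- sample.int(csize - span_len + 1L, 1L)
      cand <- GenomicRanges::GRanges(ti$chrom,
                                     IRanges::IRanges(pos, pos + span_len - 1L))
      if (!IRanges::overlapsAny(cand, excl, ignore.strand = TRUE)) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place decoy copying ", ti$transcript_id,
           " after ", config$max_attempts, " attempts")
    id <- sprintf("D%05d", d)
    rows[[d]] <- data.frame(
      chrom = ti$chrom, start = pos + offs, end = pos + offs + lens - 1L,
      strand = ti$strand, transcript_id = id, gene_id = id,
      biotype = "other", stringsAsFactors = FALSE)
    sources[d] <- ti$transcript_id
  }
  out <- lnc_annotation(do.call(rbind, rows), chrom_sizes = chrom_sizes)
  attr(out, "sources") <- data.frame(
    decoy_id = sprintf("D%05d", seq_len(config$n_decoys)),
    source_id = sources, stringsAsFactors = FALSE)
  out
}

#' Quality control of a decoy set
#'
#' @param decoys Decoy [lnc_annotation()] from [generate_decoys()].
#' @param annotation The source annotation.
#' @param buffer Buffer used at generation time.
#' @return A list: `n_overlap_violations` (decoy spans intersecting
#'   annotation spans +/- buffer; must be 0), `exon_count_match` and
#'   `exonic_length_match` (do the decoy multisets equal their sources'?),
#'   and `length_ks_stat` (two-sample Kolmogorov-Smirnov distance between
#'   decoy and full-annotation exonic-length distributions; reported, not
#'   tested).
#' @export
decoy_qc <- function(decoys, annotation, buffer = 1000L) {
  excl <- GenomicRanges::reduce(
    GenomicRanges::resize(gene_spans(annotation),
                          GenomicRanges::width(gene_spans(annotation)) +
                            2L * buffer, fix = "center"),
    ignore.strand = TRUE)
  dspan <- tx_spans(decoys)
  viol <- sum(IRanges::overlapsAny(dspan, excl, ignore.strand = TRUE))

  exonic_len <- function(ann) {
    w <- tapply(GenomicRanges::width(ann$exons),
                S4Vectors::mcols(ann$exons)$transcript_id, sum)
    as.integer(w)
  }
  src <- attr(decoys, "sources")
  ec_match <- len_match <- NA
  if (!is.null(src)) {
    stx <- annotation$transcripts[match(src$source_id,
                                        annotation$transcripts$transcript_id), ]
    dtx <- decoys$transcripts[match(src$decoy_id,
                                    decoys$transcripts$transcript_id), ]
    ec_match <- identical(sort(stx$n_exons), sort(dtx$n_exons))
    slen <- tapply(GenomicRanges::width(annotation$exons),
                   S4Vectors::mcols(annotation$exons)$transcript_id, sum)
    dlen <- tapply(GenomicRanges::width(decoys$exons),
                   S4Vectors::mcols(decoys$exons)$transcript_id, sum)
    len_match <- identical(sort(as.integer(slen[src$source_id])),
                           sort(as.integer(dlen[src$decoy_id])))
  }
  ks <- suppressWarnings(
    ks.test(exonic_len(decoys), exonic_len(annotation))$statistic)
  list(n_overlap_violations = viol, exon_count_match = ec_match,
       exonic_length_match = len_match, length_ks_stat = unname(ks))
}
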