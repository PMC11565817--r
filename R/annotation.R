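#' @import methods
#' @importFrom stats quantile rnorm rpois rlnorm rnbinom runif setNames ks.test
#' @importFrom utils read.table write.table head tail packageVersion
NULL

BIOTYPES <- c("protein_coding", "lncRNA", "pseudogene", "small_rna", "other")

#' Build an annotation from an exon table
#'
#' The central container of the pipeline: an indexed collection of gene loci
#' and their transcript models, assembled from per-exon records. Coordinates
#' are 1-based closed (GenomicRanges convention); conversion from 0-based or
#' GTF coordinates happens in the format readers, never here.
#'
#' @param exons A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (`"+"` or `"-"`; evidence-track `"."` is not allowed on transcripts),
#'   `transcript_id`, `gene_id`, and optionally `biotype` (one of
#'   `protein_coding`, `lncRNA`, `pseudogene`, `small_rna`, `other`;
#'   defaults to `other`). Alternatively a `GRanges` with the same metadata
#'   columns.
#' @param chrom_sizes Optional named integer vector of chromosome lengths;
#'   when given, exons are validated against it and the sizes are kept as
#'   `seqlengths` on the exon ranges.
#'
#' @return An object of class `lnc_annotation`: a list with elements
#'   `exons` (sorted `GRanges` with `transcript_id`/`gene_id` metadata),
#'   `transcripts` (one row per transcript: id, gene, biotype, span, exon
#'   count) and `genes` (one row per gene locus: id, biotype, span covering
#'   all member transcripts).
#' @export
lnc_annotation <- function(exons, chrom_sizes = NULL) {
  if (is(exons, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(exons)),
      start = GenomicRanges::start(exons),
      end = GenomicRanges::end(exons),
      strand = as.character(GenomicRanges::strand(exons)),
      transcript_id = S4Vectors::mcols(exons)$transcript_id,
      gene_id = S4Vectors::mcols(exons)$gene_id,
      stringsAsFactors = FALSE
    )
    if (!is.null(S4Vectors::mcols(exons)$biotype))
      df$biotype <- S4Vectors::mcols(exons)$biotype
    exons <- df
  }
  stopifnot(is.data.frame(exons))
  req <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  missing_cols <- setdiff(req, names(exons))
  if (length(missing_cols))
    stop("exon table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(exons$biotype)) exons$biotype <- "other"
  exons$biotype <- as.character(exons$biotype)
  bad_bt <- setdiff(unique(exons$biotype), BIOTYPES)
  if (length(bad_bt))
    stop("unknown biotype(s): ", paste(bad_bt, collapse = ", "))
  if (any(!exons$strand %in% c("+", "-")))
    stop("transcript exons must be stranded '+' or '-'")
  if (any(exons$end < exons$start))
    stop("exon with end < start")
  if (any(exons$start < 1))
    stop("exon start below 1")

  if (nrow(exons) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(transcript_id = character(),
                                                 gene_id = character())
    tx <- data.frame(transcript_id = character(), gene_id = character(),
                     biotype = character(), chrom = character(),
                     strand = character(), start = integer(), end = integer(),
                     n_exons = integer(), stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = character(), biotype = character(),
                        chrom = character(), strand = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
    return(structure(list(exons = gr, transcripts = tx, genes = genes),
                     class = "lnc_annotation"))
  }

  ord <- order(exons$chrom, exons$start, exons$end, exons$transcript_id)
  exons <- exons[ord, , drop = FALSE]

  # one chrom/strand/gene per transcript; exons sorted, disjoint, non-adjacent
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    sub <- exons[idx, , drop = FALSE]
    if (length(unique(sub$chrom)) != 1L || length(unique(sub$strand)) != 1L)
      stop("transcript ", sub$transcript_id[1], " spans multiple chrom/strand")
    if (length(unique(sub$gene_id)) != 1L)
      stop("transcript ", sub$transcript_id[1], " assigned to multiple genes")
    if (nrow(sub) > 1L && any(sub$start[-1] <= sub$end[-nrow(sub)] + 1L))
      stop("transcript ", sub$transcript_id[1],
           " has overlapping or adjacent exons")
  }

  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand,
    transcript_id = exons$transcript_id,
    gene_id = exons$gene_id
  )
  if (!is.null(chrom_sizes)) {
    missing_chr <- setdiff(unique(exons$chrom), names(chrom_sizes))
    if (length(missing_chr))
      stop("exons on undeclared chromosome(s): ",
           paste(missing_chr, collapse = ", "))
    if (any(exons$end > chrom_sizes[exons$chrom]))
      stop("exon end beyond declared chromosome size")
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_sizes)
  }

  tx_first <- !duplicated(exons$transcript_id)
  tx <- data.frame(
    transcript_id = exons$transcript_id[tx_first],
    gene_id = exons$gene_id[tx_first],
    biotype = exons$biotype[tx_first],
    chrom = exons$chrom[tx_first],
    strand = exons$strand[tx_first],
    stringsAsFactors = FALSE
  )
  tx$start <- as.integer(tapply(exons$start, exons$transcript_id, min)[tx$transcript_id])
  tx$end <- as.integer(tapply(exons$end, exons$transcript_id, max)[tx$transcript_id])
  tx$n_exons <- as.integer(table(exons$transcript_id)[tx$transcript_id])
  rownames(tx) <- NULL

  g_first <- !duplicated(tx$gene_id)
  genes <- data.frame(
    gene_id = tx$gene_id[g_first],
    biotype = tx$biotype[g_first],
    chrom = tx$chrom[g_first],
    strand = tx$strand[g_first],
    stringsAsFactors = FALSE
  )
  genes$start <- as.integer(tapply(tx$start, tx$gene_id, min)[genes$gene_id])
  genes$end <- as.integer(tapply(tx$end, tx$gene_id, max)[genes$gene_id])
  rownames(genes) <- NULL
  gchk <- split(tx[, c("chrom", "strand")], tx$gene_id)
  for (nm in names(gchk))
    if (nrow(unique(gchk[[nm]])) != 1L)
      stop("gene ", nm, " has transcripts on multiple chrom/strand")

  structure(list(exons = gr, transcripts = tx, genes = genes),
            class = "lnc_annotation")
}

#' @export
print.lnc_annotation <- function(x, ...) {
  cat(sprintf("lnc_annotation: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), length(x$exons)))
  bt <- table(x$genes$biotype)
  cat("  gene biotypes:",
      paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  invisible(x)
}

#' Number of transcripts / genes in an annotation
#' @param ann An `lnc_annotation`.
#' @return Integer count.
#' @export
n_transcripts <- function(ann) nrow(ann$transcripts)

#' @rdname n_transcripts
#' @export
n_genes <- function(ann) nrow(ann$genes)

#' Restrict an annotation to a set of transcripts
#' @param ann An `lnc_annotation`.
#' @param transcript_ids Character vector of transcript ids to keep.
#' @return A new `lnc_annotation` (gene table recomputed from the survivors).
#' @export
ann_subset <- function(ann, transcript_ids) {
  keep <- S4Vectors::mcols(ann$exons)$transcript_id %in% transcript_ids
  gr <- ann$exons[keep]
  bt <- setNames(ann$transcripts$biotype, ann$transcripts$transcript_id)
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = S4Vectors::mcols(gr)$transcript_id,
    gene_id = S4Vectors::mcols(gr)$gene_id,
    biotype = unname(bt[S4Vectors::mcols(gr)$transcript_id]),
    stringsAsFactors = FALSE
  )
  sizes <- GenomeInfoDb::seqlengths(ann$exons)
  if (all(is.na(sizes))) sizes <- NULL
  lnc_annotation(df, chrom_sizes = sizes)
}

#' Exons grouped per transcript
#' @param ann An `lnc_annotation`.
#' @return A `GRangesList`, one element per transcript, exons sorted by start.
#' @export
exons_by_tx <- function(ann) {
  GenomicRanges::split(ann$exons, S4Vectors::mcols(ann$exons)$transcript_id)
}

#' Transcript spans as GRanges
#' @param ann An `lnc_annotation`.
#' @return `GRanges` named by transcript id, one range per transcript.
#' @export
tx_spans <- function(ann) {
  tx <- ann$transcripts
  gr <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start, tx$end),
                               strand = tx$strand,
                               transcript_id = tx$transcript_id,
                               gene_id = tx$gene_id, biotype = tx$biotype)
  names(gr) <- tx$transcript_id
  gr
}

#' Gene locus spans as GRanges
#' @param ann An `lnc_annotation`.
#' @return `GRanges` named by gene id, one range per gene locus.
#' @export
gene_spans <- function(ann) {
  g <- ann$genes
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                               strand = g$strand,
                               gene_id = g$gene_id, biotype = g$biotype)
  names(gr) <- g$gene_id
  gr
}

#' Introns of every transcript
#'
#' Introns are the gaps between consecutive exons. Keys are 1-based closed
#' intron coordinates; the junction-table file format uses 0-based half-open
#' donor/acceptor offsets, converted on read/write.
#'
#' @param ann An `lnc_annotation`.
#' @return A `data.frame` with columns `transcript_id`, `chrom`, `strand`,
#'   `intron_start`, `intron_end` (1-based closed). Monoexonic transcripts
#'   contribute no rows.
#' @export
introns_of <- function(ann) {
  gr <- ann$exons
  df <- data.frame(
    transcript_id = S4Vectors::mcols(gr)$transcript_id,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  same_tx <- df$transcript_id[-1] == df$transcript_id[-nrow(df)]
  if (nrow(df) < 2L || !any(same_tx)) {
    return(data.frame(transcript_id = character(), chrom = character(),
                      strand = character(), intron_start = integer(),
                      intron_end = integer(), stringsAsFactors = FALSE))
  }
  i <- which(same_tx)
  data.frame(
    transcript_id = df$transcript_id[i],
    chrom = df$chrom[i],
    strand = df$strand[i],
    intron_start = df$end[i] + 1L,
    intron_end = df$start[i + 1L] - 1L,
    stringsAsFactors = FALSE
  )
}

#' Canonical splice-junction key
#'
#' Uniquely identifies a junction by chromosome, strand and 1-based closed
#' intron coordinates.
#'
#' @param chrom,strand,intron_start,intron_end Vectors of equal length.
#' @return Character vector of keys.
#' @export
junction_key <- function(chrom, strand, intron_start, intron_end) {
  sprintf("%s:%s:%d-%d", chrom, strand,
          as.integer(intron_start), as.integer(intron_end))
}
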