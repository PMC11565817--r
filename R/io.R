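# Format boundaries: GTF/BED/bedGraph through rtracklayer, FASTA through
# Biostrings, the 5-column junction table through base R. All readers emit
# 1-based closed internal coordinates; the junction TSV keeps its documented
# 0-based half-open donor/acceptor layout on disk.

#' Read a gene annotation from GTF
#'
#' Assembles transcripts and gene loci from `exon` feature lines. Both the
#' GENCODE attribute dialect (`gene_id "g1"; transcript_id "t1";`) and the
#' GFF-style `key=value` dialect are accepted on read; [write_gtf()] always
#' emits the GENCODE dialect. Gene biotype is taken from a `gene_biotype`,
#' `gene_type` or `biotype` attribute when present, else `"other"`.
#'
#' @param path Path to a GTF (or GFF with exon features) file.
#' @param chrom_sizes Optional named vector of chromosome sizes for
#'   validation.
#' @return An [lnc_annotation()].
#' @export
read_gtf <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path, n = 200L)
  data_lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fmt <- "gtf"
  if (length(data_lines)) {
    attr_field <- vapply(strsplit(data_lines, "\t"), function(x)
      if (length(x) >= 9L) x[9L] else "", character(1))
    if (!any(grepl("\\w+ +\"", attr_field)) && any(grepl("=", attr_field)))
      fmt <- "gff3"
  }
  gr <- rtracklayer::import(path, format = fmt)
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L)
    stop("no exon features found in ", path)
  mc <- S4Vectors::mcols(gr)
  bt_col <- intersect(c("gene_biotype", "gene_type", "biotype"), names(mc))
  bt <- if (length(bt_col)) as.character(mc[[bt_col[1]]]) else rep(NA_character_, length(gr))
  bt[is.na(bt) | !(bt %in% BIOTYPES)] <- "other"
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    biotype = bt,
    stringsAsFactors = FALSE
  )
  if (anyNA(df$transcript_id) || anyNA(df$gene_id))
    stop("exon feature lacking gene_id/transcript_id attribute in ", path)
  lnc_annotation(df, chrom_sizes = chrom_sizes)
}

#' Write an annotation to GTF
#'
#' Emits gene, transcript and exon lines in the GENCODE attribute dialect,
#' 1-based inclusive coordinates, ordered by (chrom, gene start, gene_id,
#' transcript start, transcript_id) so output is deterministic.
#'
#' @param ann An [lnc_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  fmt_attr <- function(gene_id, biotype, transcript_id = NULL) {
    a <- sprintf('gene_id "%s"; gene_biotype "%s";', gene_id, biotype)
    if (!is.null(transcript_id))
      a <- sprintf('%s transcript_id "%s";', a, transcript_id)
    a
  }
  rows <- character(0)
  g <- ann$genes[order(ann$genes$chrom, ann$genes$start, ann$genes$gene_id), ,
                 drop = FALSE]
  tx <- ann$transcripts
  ex <- ann$exons
  ex_tx <- S4Vectors::mcols(ex)$transcript_id
  line <- function(chrom, feat, start, end, strand, attrs)
    sprintf("%s\tlncforge\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, start, end, strand, attrs)
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    gl <- line(gi$chrom, "gene", gi$start, gi$end, gi$strand,
               fmt_attr(gi$gene_id, gi$biotype))
    txs <- tx[tx$gene_id == gi$gene_id, , drop = FALSE]
    txs <- txs[order(txs$start, txs$transcript_id), , drop = FALSE]
    tl <- character(0)
    for (j in seq_len(nrow(txs))) {
      tj <- txs[j, ]
      tl <- c(tl, line(tj$chrom, "transcript", tj$start, tj$end, tj$strand,
                       fmt_attr(tj$gene_id, tj$biotype, tj$transcript_id)))
      e <- ex[ex_tx == tj$transcript_id]
      e <- e[order(GenomicRanges::start(e))]
      tl <- c(tl, line(tj$chrom, "exon", GenomicRanges::start(e),
                       GenomicRanges::end(e), tj$strand,
                       fmt_attr(tj$gene_id, tj$biotype, tj$transcript_id)))
    }
    out[[i]] <- c(gl, tl)
  }
  writeLines(c("##format: gtf", unlist(out)), path)
  invisible(path)
}

#' Read an interval evidence track (BED or bedGraph)
#'
#' BED columns 4/5/6 become `label`/`score`/strand; a missing strand column
#' yields unstranded (`*`) intervals. bedGraph intervals carry `score` only.
#'
#' @param path Path to the track file.
#' @param kind `"bed"` or `"bedgraph"`.
#' @return A `GRanges`, sorted, with optional `label` and `score` metadata.
#' @export
read_track <- function(path, kind = c("bed", "bedgraph")) {
  kind <- match.arg(kind)
  gr <- rtracklayer::import(path,
                            format = if (kind == "bed") "bed" else "bedGraph")
  if (kind == "bed" && !is.null(S4Vectors::mcols(gr)$name)) {
    S4Vectors::mcols(gr)$label <- S4Vectors::mcols(gr)$name
    S4Vectors::mcols(gr)$name <- NULL
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write an interval track as BED
#'
#' @param gr `GRanges` with optional `label` and `score` metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(gr, path) {
  out <- gr
  if (!is.null(S4Vectors::mcols(out)$label)) {
    S4Vectors::mcols(out)$name <- S4Vectors::mcols(out)$label
    S4Vectors::mcols(out)$label <- NULL
  }
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Write a per-base score track as bedGraph
#' @param gr `GRanges` with a numeric `score` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write genome sequence (FASTA)
#' @param path FASTA path.
#' @return A `DNAStringSet` named by chromosome (first word of each header).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' @rdname read_fasta
#' @param seqs A named `DNAStringSet`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read splice-junction short-read support counts
#'
#' The file is a headerless 5-column TSV: chrom, strand, donor (0-based
#' intron start), acceptor (0-based exclusive intron end), read count. An
#' absent junction semantically has count 0 ([junction_count()]).
#'
#' @param path TSV path.
#' @return A named integer vector of class `junction_support`, keyed by
#'   [junction_key()] (1-based closed intron coordinates).
#' @export
read_junction_support <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "strand", "donor", "acceptor", "count"),
                   colClasses = c("character", "character", "integer",
                                  "integer", "integer"))
  if (any(df$count < 0))
    stop("negative junction read count in ", path)
  if (any(df$donor >= df$acceptor))
    stop("junction with donor >= acceptor in ", path)
  x <- setNames(df$count,
                junction_key(df$chrom, df$strand, df$donor + 1L, df$acceptor))
  class(x) <- "junction_support"
  x
}

#' @rdname read_junction_support
#' @param support A `junction_support` vector.
#' @export
write_junction_support <- function(support, path) {
  parts <- regmatches(names(support),
                      regexec("^(.*):([+-.]):(\\d+)-(\\d+)$", names(support)))
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 2L),
    strand = vapply(parts, `[`, "", 3L),
    donor = as.integer(vapply(parts, `[`, "", 4L)) - 1L,
    acceptor = as.integer(vapply(parts, `[`, "", 5L)),
    count = as.integer(support)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Look up junction read counts
#' @param support A `junction_support` vector.
#' @param keys Character keys from [junction_key()].
#' @return Integer counts; 0 for junctions absent from the table.
#' @export
junction_count <- function(support, keys) {
  out <- unclass(support)[keys]
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Read chromosome sizes from a 2-column TSV
#' @param path Path to a `chrom<TAB>size` file.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "integer"))
  setNames(df$size, df$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes Named integer vector of chromosome sizes.
#' @export
write_chrom_sizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), as.integer(sizes)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
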