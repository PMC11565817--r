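# UCSC chain alignments. A chain maps an ungapped-block alignment from a
# source ("target" in UCSC header parlance) to a target ("query") sequence.
# Block offsets are stored in native chain coordinates (0-based half-open;
# minus-orientation target offsets live on the reversed target sequence).
# Conversion to the package's 1-based closed convention happens only inside
# project_interval().

new_chain <- function(id, score, src_chrom, src_size, src_start, src_end,
                      tgt_chrom, tgt_size, tgt_strand, tgt_start, tgt_end,
                      blocks) {
  structure(list(id = id, score = score,
                 src_chrom = src_chrom, src_size = src_size,
                 src_start = src_start, src_end = src_end,
                 tgt_chrom = tgt_chrom, tgt_size = tgt_size,
                 tgt_strand = tgt_strand,
                 tgt_start = tgt_start, tgt_end = tgt_end,
                 blocks = blocks),
            class = "chain_alignment")
}

#' @export
print.chain_alignment <- function(x, ...) {
  cat(sprintf("chain %s (score %s): %s:%d-%d -> %s:%d-%d (%s), %d block(s)\n",
              x$id, format(x$score), x$src_chrom, x$src_start, x$src_end,
              x$tgt_chrom, x$tgt_start, x$tgt_end, x$tgt_strand,
              nrow(x$blocks)))
  invisible(x)
}

#' Read pairwise genome alignments in UCSC chain format
#'
#' Reconstructs ungapped alignment blocks from the size/dt/dq triples and
#' validates their cumulative spans against the header coordinates.
#'
#' @param path Path to a chain file.
#' @return A list of `chain_alignment` objects. Each holds the source and
#'   target chromosome/size/span, target orientation (`+`/`-`), chain id and
#'   score, and a `blocks` data frame with 0-based `src`/`tgt` offsets and
#'   `size` per ungapped block.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    f <- strsplit(ln, "\\s+")[[1]]
    if (f[1] != "chain" || length(f) < 13L)
      stop("malformed chain header at line ", i)
    hdr <- list(score = as.numeric(f[2]),
                src_chrom = f[3], src_size = as.integer(f[4]),
                src_strand = f[5],
                src_start = as.integer(f[6]), src_end = as.integer(f[7]),
                tgt_chrom = f[8], tgt_size = as.integer(f[9]),
                tgt_strand = f[10],
                tgt_start = as.integer(f[11]), tgt_end = as.integer(f[12]),
                id = f[13])
    if (hdr$src_strand != "+")
      stop("chain ", hdr$id, ": source strand must be '+'")
    src_off <- hdr$src_start
    tgt_off <- hdr$tgt_start
    src <- integer(0); tgt <- integer(0); size <- integer(0)
    repeat {
      i <- i + 1L
      if (i > length(lines)) stop("chain ", hdr$id, ": truncated block list")
      b <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      b <- as.integer(b)
      src <- c(src, src_off); tgt <- c(tgt, tgt_off); size <- c(size, b[1])
      if (length(b) == 1L) break
      src_off <- src_off + b[1] + b[2]
      tgt_off <- tgt_off + b[1] + b[3]
    }
    if (src[length(src)] + size[length(size)] != hdr$src_end)
      stop("chain ", hdr$id, ": block sum mismatch with source span")
    if (tgt[length(tgt)] + size[length(size)] != hdr$tgt_end)
      stop("chain ", hdr$id, ": block sum mismatch with target span")
    if (hdr$src_end > hdr$src_size || hdr$tgt_end > hdr$tgt_size)
      stop("chain ", hdr$id, ": span exceeds declared chromosome size")
    chains[[length(chains) + 1L]] <- new_chain(
      hdr$id, hdr$score, hdr$src_chrom, hdr$src_size, hdr$src_start,
      hdr$src_end, hdr$tgt_chrom, hdr$tgt_size, hdr$tgt_strand,
      hdr$tgt_start, hdr$tgt_end,
      data.frame(src = src, tgt = tgt, size = size))
    i <- i + 1L
  }
  chains
}

#' @rdname read_chain
#' @param chains A list of `chain_alignment` objects.
#' @export
write_chain <- function(chains, path) {
  if (is(chains, "chain_alignment")) chains <- list(chains)
  out <- character(0)
  for (ch in chains) {
    b <- ch$blocks
    hdr <- sprintf("chain %s %s %d + %d %d %s %d %s %d %d %s",
                   format(ch$score, scientific = FALSE),
                   ch$src_chrom, ch$src_size, ch$src_start, ch$src_end,
                   ch$tgt_chrom, ch$tgt_size, ch$tgt_strand,
                   ch$tgt_start, ch$tgt_end, ch$id)
    n <- nrow(b)
    body <- if (n == 1L) as.character(b$size) else {
      dt <- b$src[-1] - (b$src[-n] + b$size[-n])
      dq <- b$tgt[-1] - (b$tgt[-n] + b$size[-n])
      c(sprintf("%d\t%d\t%d", b$size[-n], dt, dq), as.character(b$size[n]))
    }
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Invert a chain alignment
#'
#' Returns the chain mapping target to source, so that projections can be
#' run in both directions from one file. Inverting twice is the identity.
#'
#' @param chain A `chain_alignment`.
#' @return A `chain_alignment` with source and target swapped.
#' @export
chain_invert <- function(chain) {
  b <- chain$blocks
  if (chain$tgt_strand == "+") {
    nb <- data.frame(src = b$tgt, tgt = b$src, size = b$size)
    nb <- nb[order(nb$src), , drop = FALSE]
    rownames(nb) <- NULL
    new_chain(chain$id, chain$score,
              chain$tgt_chrom, chain$tgt_size, chain$tgt_start, chain$tgt_end,
              chain$src_chrom, chain$src_size, "+",
              chain$src_start, chain$src_end, nb)
  } else {
    # forward-strand coords of old target become the new source; the new
    # target (old source) is then reported on its reversed strand
    nb <- data.frame(src = chain$tgt_size - (b$tgt + b$size),
                     tgt = chain$src_size - (b$src + b$size),
                     size = b$size)
    nb <- nb[order(nb$src), , drop = FALSE]
    rownames(nb) <- NULL
    new_chain(chain$id, chain$score,
              chain$tgt_chrom, chain$tgt_size,
              chain$tgt_size - chain$tgt_end, chain$tgt_size - chain$tgt_start,
              chain$src_chrom, chain$src_size, "-",
              chain$src_size - chain$src_end, chain$src_size - chain$src_start,
              nb)
  }
}

flip_strand <- function(s) c(`+` = "-", `-` = "+", `*` = "*", `.` = ".")[s]

#' Project genomic intervals through a chain (liftover semantics)
#'
#' Each interval is intersected with the chain's ungapped blocks and carried
#' to the target by offset arithmetic; bases falling in alignment gaps are
#' dropped. For minus-orientation chains the reversed-target coordinates are
#' converted to forward-strand coordinates and the fragment strand is
#' flipped relative to the query.
#'
#' @param chain A `chain_alignment`.
#' @param iv A `GRanges` of query intervals (any length). Intervals on a
#'   chromosome other than the chain's source map to nothing (empty result,
#'   not an error).
#' @return A list of class `projection_result`: `fragments` (a `GRanges` on
#'   the target genome with a `query` index column), and `mapped_fraction`
#'   (numeric per input interval: mapped bp / interval bp).
#' @export
project_interval <- function(chain, iv) {
  stopifnot(is(iv, "GRanges"))
  b <- chain$blocks
  frag_chrom <- character(0); frag_start <- integer(0)
  frag_end <- integer(0); frag_strand <- character(0); frag_q <- integer(0)
  mapped <- numeric(length(iv))
  qchrom <- as.character(GenomeInfoDb::seqnames(iv))
  qstrand <- as.character(GenomicRanges::strand(iv))
  for (k in seq_along(iv)) {
    if (qchrom[k] != chain$src_chrom) next
    s0 <- GenomicRanges::start(iv)[k] - 1L
    e0 <- GenomicRanges::end(iv)[k]
    o1 <- pmax(s0, b$src)
    o2 <- pmin(e0, b$src + b$size)
    hit <- which(o1 < o2)
    if (!length(hit)) next
    t0 <- b$tgt[hit] + (o1[hit] - b$src[hit])
    t1 <- b$tgt[hit] + (o2[hit] - b$src[hit])
    if (chain$tgt_strand == "+") {
      fs <- t0 + 1L; fe <- t1
      st <- qstrand[k]
    } else {
      fs <- chain$tgt_size - t1 + 1L; fe <- chain$tgt_size - t0
      st <- unname(flip_strand(qstrand[k]))
    }
    mapped[k] <- sum(o2[hit] - o1[hit]) / (e0 - s0)
    frag_chrom <- c(frag_chrom, rep(chain$tgt_chrom, length(hit)))
    frag_start <- c(frag_start, as.integer(fs))
    frag_end <- c(frag_end, as.integer(fe))
    frag_strand <- c(frag_strand, rep(st, length(hit)))
    frag_q <- c(frag_q, rep(k, length(hit)))
  }
  fragments <- GenomicRanges::GRanges(
    seqnames = frag_chrom,
    ranges = IRanges::IRanges(frag_start, frag_end),
    strand = frag_strand, query = frag_q)
  fragments <- GenomicRanges::sort(fragments, ignore.strand = TRUE)
  structure(list(fragments = fragments, mapped_fraction = mapped),
            class = "projection_result")
}
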