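# Shared fixtures. Everything is built in code; the synthetic bundle and
# the demo run are simulated once per session and reused across files.

.shared <- new.env(parent = emptyenv())

shared_bundle <- function() {
  if (is.null(.shared$bundle))
    .shared$bundle <- simulate_bundle(sim_config(seed = 42))
  .shared$bundle
}

shared_demo <- function() {
  if (is.null(.shared$demo))
    .shared$demo <- run_demo(42, bundle = shared_bundle(), n_decoys = 200L)
  .shared$demo
}

# one transcript's exon table from a list of c(start, end) pairs
tx_rows <- function(tx_id, exons, chrom = "chr1", strand = "+",
                    gene_id = tx_id, biotype = "other") {
  do.call(rbind, lapply(exons, function(e)
    data.frame(chrom = chrom, start = e[1], end = e[2], strand = strand,
               transcript_id = tx_id, gene_id = gene_id, biotype = biotype,
               stringsAsFactors = FALSE)))
}

mk_ann <- function(..., chrom_sizes = NULL) {
  lnc_annotation(do.call(rbind, list(...)), chrom_sizes = chrom_sizes)
}

# single-chain helper in native chain coordinates (0-based block offsets)
mk_chain <- function(blocks, src_size = 20000L, tgt_size = 20000L,
                     tgt_strand = "+", id = "1", score = 100,
                     src_chrom = "chr1", tgt_chrom = "chr1") {
  b <- as.data.frame(blocks)
  names(b) <- c("src", "tgt", "size")
  b[] <- lapply(b, as.integer)
  rownames(b) <- NULL
  lncforge:::new_chain(id, score, src_chrom, src_size,
                       b$src[1], b$src[nrow(b)] + b$size[nrow(b)],
                       tgt_chrom, tgt_size, tgt_strand,
                       b$tgt[1], b$tgt[nrow(b)] + b$size[nrow(b)], b)
}

# independent per-base projection oracle: enumerates the target position of
# every aligned source base directly from the block table
per_base_map <- function(chain) {
  src <- integer(0); tgt <- integer(0)
  for (i in seq_len(nrow(chain$blocks))) {
    b <- chain$blocks[i, ]
    s <- b$src + seq_len(b$size)          # 1-based source positions
    t0 <- b$tgt + seq_len(b$size) - 1L    # 0-based target offsets
    if (chain$tgt_strand == "-") t0 <- chain$tgt_size - t0 - 1L
    src <- c(src, s); tgt <- c(tgt, t0 + 1L)
  }
  setNames(tgt, src)
}

# random spliced/monoexonic models drawing chains from a limited pool so
# that chain collisions (merge groups) actually occur
random_models <- function(n, seed, n_pool = 40L) {
  set.seed(seed)
  pool <- lapply(seq_len(n_pool), function(i) {
    n_ex <- 1L + sample(0:3, 1L)
    estart <- cumsum(c(sample(1000:50000, 1L),
                       if (n_ex > 1L) sample(200:900, n_ex - 1L) + 100L))
    elen <- sample(120:300, n_ex, replace = TRUE)
    list(chrom = sample(c("chrA", "chrB"), 1L),
         strand = sample(c("+", "-"), 1L),
         starts = estart, ends = estart + elen)
  })
  rows <- lapply(seq_len(n), function(i) {
    p <- pool[[sample.int(n_pool, 1L)]]
    s <- p$starts; e <- p$ends
    k <- length(s)
    # jitter termini only; internal boundaries identical across draws
    s[1] <- max(1L, s[1] + sample(-50:50, 1L))
    if (k == 1L) e[1] <- e[1] + sample(-50:50, 1L)
    else e[k] <- e[k] + sample(-50:50, 1L)
    data.frame(chrom = p$chrom, start = s, end = e, strand = p$strand,
               transcript_id = sprintf("r%04d", i),
               gene_id = sprintf("r%04d", i), biotype = "other",
               stringsAsFactors = FALSE)
  })
  lnc_annotation(do.call(rbind, rows))
}

# O(n^2) grouping oracle: pairwise comparison of per-model junction lists
merge_oracle_groups <- function(ann) {
  tx_ids <- ann$transcripts$transcript_id
  n <- length(tx_ids)
  ex <- as.data.frame(ann$exons)
  chains <- lapply(tx_ids, function(id) {
    e <- ex[ex$transcript_id == id, ]
    e <- e[order(e$start), ]
    list(chrom = e$seqnames[1], strand = e$strand[1],
         span = c(min(e$start), max(e$end)),
         donors = if (nrow(e) > 1) e$end[-nrow(e)] + 1L else integer(0),
         acceptors = if (nrow(e) > 1) e$start[-1] - 1L else integer(0))
  })
  same_group <- function(a, b) {
    if (a$chrom != b$chrom || a$strand != b$strand) return(FALSE)
    if (length(a$donors) || length(b$donors))
      return(identical(a$donors, b$donors) &&
               identical(a$acceptors, b$acceptors))
    ov <- min(a$span[2], b$span[2]) - max(a$span[1], b$span[1]) + 1L
    wa <- a$span[2] - a$span[1] + 1L
    wb <- b$span[2] - b$span[1] + 1L
    ov >= 0.5 * wa && ov >= 0.5 * wb
  }
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (same_group(chains[[i]], chains[[j]])) {
      pairs_a <- c(pairs_a, i); pairs_b <- c(pairs_b, j)
    }
  comp <- lncforge:::components_of_pairs(n, pairs_a, pairs_b)
  split(tx_ids, comp)
}

# canonical form of a grouping for set comparison
canon_groups <- function(groups) {
  unname(sort(vapply(groups, function(g) paste(sort(g), collapse = ","), "")))
}
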