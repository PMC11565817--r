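# Chain projection, inversion, candidate search and strict reciprocal
# orthology calls.

test_that("projection maps offsets through plus-orientation blocks", {
  ch <- mk_chain(rbind(c(100, 1100, 100)))
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160),
                               strand = "+")
  pr <- project_interval(ch, iv)
  expect_equal(GenomicRanges::start(pr$fragments), 1151L)
  expect_equal(GenomicRanges::end(pr$fragments), 1160L)
  expect_equal(pr$mapped_fraction, 1.0)

  iv2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(91, 110))
  pr2 <- project_interval(ch, iv2)
  expect_equal(GenomicRanges::start(pr2$fragments), 1101L)
  expect_equal(GenomicRanges::end(pr2$fragments), 1110L)
  expect_equal(pr2$mapped_fraction, 0.5)

  off <- GenomicRanges::GRanges("chrX", IRanges::IRanges(151, 160))
  pr3 <- project_interval(ch, off)
  expect_equal(length(pr3$fragments), 0L)
  expect_equal(pr3$mapped_fraction, 0)
})

test_that("projection equals the per-base oracle, including minus chains", {
  chains <- list(
    mk_chain(rbind(c(100, 300, 100)), tgt_strand = "-", tgt_size = 2000L),
    mk_chain(rbind(c(0, 500, 120), c(200, 700, 80), c(400, 1000, 300)),
             src_size = 10000L, tgt_size = 10000L),
    mk_chain(rbind(c(50, 900, 200), c(400, 1300, 150), c(700, 1500, 100)),
             tgt_strand = "-", src_size = 5000L, tgt_size = 3000L))
  set.seed(31)
  for (ch in chains) {
    oracle <- per_base_map(ch)
    span <- c(ch$src_start + 1L, ch$src_end)
    # exhaustive width-1 projection over the full source span
    pos <- seq(span[1], span[2])
    iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos),
                                 strand = "+")
    pr <- project_interval(ch, iv)
    got <- setNames(rep(NA_integer_, length(pos)), pos)
    q <- S4Vectors::mcols(pr$fragments)$query
    got[q] <- GenomicRanges::start(pr$fragments)
    want <- setNames(rep(NA_integer_, length(pos)), pos)
    want[names(oracle)[as.integer(names(oracle)) >= span[1]]] <-
      oracle[as.integer(names(oracle)) >= span[1]]
    expect_identical(got, want)
    expect_equal(unname(is.na(got)), pr$mapped_fraction == 0)

    # random multi-base intervals: fragment base sets match the oracle
    for (r in 1:25) {
      s <- sample(span[1]:span[2], 1L)
      e <- min(span[2], s + sample(1:500, 1L))
      pr2 <- project_interval(
        ch, GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e)))
      bases <- sort(unlist(Map(seq, GenomicRanges::start(pr2$fragments),
                               GenomicRanges::end(pr2$fragments))))
      want2 <- sort(unname(oracle[as.character(s:e)]))
      expect_identical(as.integer(bases), as.integer(want2[!is.na(want2)]))
      expect_equal(pr2$mapped_fraction, sum(!is.na(oracle[as.character(s:e)])) /
                     (e - s + 1))
    }
  }
})

test_that("projection agrees with rtracklayer liftOver on plus chains", {
  ch <- mk_chain(rbind(c(0, 500, 120), c(200, 700, 80), c(400, 1000, 300)),
                 src_size = 10000L, tgt_size = 10000L)
  f <- withr::local_tempfile(fileext = ".chain")
  write_chain(list(ch), f)
  rt <- rtracklayer::import.chain(f)
  set.seed(8)
  for (r in 1:10) {
    s <- sample(1:700, 1L); e <- s + sample(1:100, 1L)
    iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
    mine <- project_interval(ch, iv)$fragments
    theirs <- unlist(rtracklayer::liftOver(iv, rt))
    expect_identical(sort(GenomicRanges::start(mine)),
                     sort(GenomicRanges::start(theirs)))
    expect_identical(sort(GenomicRanges::end(mine)),
                     sort(GenomicRanges::end(theirs)))
  }
})

test_that("chain inversion is an involution and inverts the mapping", {
  for (ch in list(mk_chain(rbind(c(100, 300, 50), c(200, 400, 80))),
                  mk_chain(rbind(c(100, 300, 50), c(200, 400, 80)),
                           tgt_strand = "-", tgt_size = 2000L))) {
    inv <- chain_invert(ch)
    back <- chain_invert(inv)
    expect_equal(back[sort(names(back))], ch[sort(names(ch))])
    # forward then backward projection returns the source interval
    iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(120, 140),
                                 strand = "+")
    fwd <- project_interval(ch, iv)$fragments
    ret <- project_interval(inv, fwd)$fragments
    expect_equal(GenomicRanges::start(ret), 120L)
    expect_equal(GenomicRanges::end(ret), 140L)
    expect_equal(as.character(GenomicRanges::strand(ret)), "+")
  }
})

test_that("candidate orthologs demand correct-strand exon overlap", {
  src <- mk_ann(tx_rows("a1.t", list(c(101, 200), c(301, 400)),
                        gene_id = "a1", strand = "+"))
  identity_chain <- mk_chain(rbind(c(0, 0, 1000)))
  tgt_same <- mk_ann(tx_rows("b1.t", list(c(101, 200), c(301, 400)),
                             gene_id = "b1", strand = "+"))
  tgt_anti <- mk_ann(tx_rows("b2.t", list(c(101, 200), c(301, 400)),
                             gene_id = "b2", strand = "-"))
  hit <- candidate_orthologs(src, "a1", tgt_same, list(identity_chain))
  expect_equal(hit$target_gene, "b1")
  expect_equal(hit$fraction, 1.0)
  expect_equal(nrow(candidate_orthologs(src, "a1", tgt_anti,
                                        list(identity_chain))), 0L)
})

test_that("the overlap-fraction threshold gates split candidates", {
  src <- mk_ann(tx_rows("a1.t", list(c(1, 1000)), gene_id = "a1"))
  identity_chain <- mk_chain(rbind(c(0, 0, 2000)))
  # 60/40 split over two target genes at threshold 0.5 -> one candidate
  tgt <- mk_ann(tx_rows("b1.t", list(c(1, 600)), gene_id = "b1"),
                tx_rows("b2.t", list(c(601, 1000)), gene_id = "b2"))
  hit <- candidate_orthologs(src, "a1", tgt, list(identity_chain))
  expect_equal(hit$target_gene, "b1")
  hit2 <- candidate_orthologs(src, "a1", tgt, list(identity_chain),
                              orthology_params(min_exon_overlap_fraction = 0.3))
  expect_setequal(hit2$target_gene, c("b1", "b2"))
})

test_that("identity chains give one-to-one self-orthology", {
  b <- shared_bundle()
  lnc <- subset_biotype(b$reference_a, "lncRNA")
  idchains <- lapply(names(b$chrom_sizes_a), function(ch)
    mk_chain(rbind(c(0, 0, b$chrom_sizes_a[[ch]])),
             src_size = b$chrom_sizes_a[[ch]],
             tgt_size = b$chrom_sizes_a[[ch]],
             src_chrom = ch, tgt_chrom = ch, id = ch))
  res <- reciprocal_orthology(lnc, lnc, idchains, idchains)
  calls_a <- res$calls[res$calls$genome == "A", ]
  expect_true(all(calls_a$class == "one_to_one"))
  expect_identical(calls_a$partners, calls_a$gene)
})

test_that("strict reciprocity drops one-way candidates", {
  # a1 projects onto b1, but b1 projects onto a2 (shifted chain back):
  # no reciprocal edge, both genes end up unpaired
  a <- mk_ann(tx_rows("a1.t", list(c(101, 300)), gene_id = "a1"),
              tx_rows("a2.t", list(c(1101, 1300)), gene_id = "a2"))
  b <- mk_ann(tx_rows("b1.t", list(c(101, 300)), gene_id = "b1"))
  ab <- mk_chain(rbind(c(0, 0, 2000)))
  ba <- mk_chain(rbind(c(0, 1000, 500)))  # b1 lands on a2
  res <- reciprocal_orthology(a, b, list(ab), list(ba))
  expect_equal(nrow(res$edges), 0L)
  expect_true(all(res$calls$class == "none"))
})

test_that("bipartite components label one-to-many relations", {
  a <- mk_ann(tx_rows("a1.t", list(c(101, 300)), gene_id = "a1"))
  b <- mk_ann(tx_rows("b1.t", list(c(101, 300)), gene_id = "b1"),
              tx_rows("b2.t", list(c(121, 320)), gene_id = "b2"))
  id <- mk_chain(rbind(c(0, 0, 2000)))
  res <- reciprocal_orthology(a, b, list(id), list(id))
  expect_setequal(res$edges$gene_b, c("b1", "b2"))
  expect_true(all(res$edges$class == "one_to_many"))
  expect_equal(res$calls$partners[res$calls$gene == "a1"], "b1,b2")
})

test_that("planted orthology classes recover exactly on the genome pair", {
  b <- shared_bundle()
  lnc_a <- subset_biotype(b$reference_a, "lncRNA")
  lnc_b <- subset_biotype(b$reference_b, "lncRNA")
  res <- reciprocal_orthology(lnc_a, lnc_b, b$chains_ab, b$chains_ba)
  calls_a <- res$calls[res$calls$genome == "A", ]
  tr <- merge(b$truth$orthologs, calls_a, by.x = "gene_a", by.y = "gene")
  expect_equal(nrow(tr), nrow(b$truth$orthologs))
  expect_identical(tr$class.y, tr$class.x)
  expect_identical(tr$partners.y, tr$partners.x)

  # the edge relation is symmetric under direction swap
  swapped <- reciprocal_orthology(lnc_b, lnc_a, b$chains_ba, b$chains_ab)
  e1 <- sort(paste(res$edges$gene_a, res$edges$gene_b))
  e2 <- sort(paste(swapped$edges$gene_b, swapped$edges$gene_a))
  expect_identical(e1, e2)
})

test_that("orthology calls are invariant to gene ordering", {
  b <- shared_bundle()
  lnc_a <- subset_biotype(b$reference_a, "lncRNA")
  lnc_b <- subset_biotype(b$reference_b, "lncRNA")
  # reverse the gene table order; calls must not change
  lnc_a_rev <- lnc_a
  lnc_a_rev$genes <- lnc_a$genes[rev(seq_len(nrow(lnc_a$genes))), ]
  r1 <- reciprocal_orthology(lnc_a, lnc_b, b$chains_ab, b$chains_ba)
  r2 <- reciprocal_orthology(lnc_a_rev, lnc_b, b$chains_ab, b$chains_ba)
  o1 <- r1$calls[order(r1$calls$genome, r1$calls$gene), ]
  o2 <- r2$calls[order(r2$calls$genome, r2$calls$gene), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("disease lookup reports per-gene classes and the fraction", {
  b <- shared_bundle()
  lnc_a <- subset_biotype(b$reference_a, "lncRNA")
  lnc_b <- subset_biotype(b$reference_b, "lncRNA")
  res <- reciprocal_orthology(lnc_a, lnc_b, b$chains_ab, b$chains_ba)
  tr <- b$truth$orthologs
  with_o <- tr$gene_a[tr$class != "none"]
  without <- tr$gene_a[tr$class == "none"]
  lst <- data.frame(gene_id = c(with_o[1], without[seq_len(3)]))
  lk <- disease_ortholog_lookup(res, lst)
  expect_equal(lk$fraction_with_ortholog, 0.25)
  expect_equal(lk$n_listed, 4L)

  empty <- disease_ortholog_lookup(res, data.frame(gene_id = character()))
  expect_equal(empty$n_listed, 0L)
  missing <- disease_ortholog_lookup(res, data.frame(gene_id = "nope"))
  expect_equal(missing$table$class, "not_in_annotation")
  expect_equal(missing$n_with_ortholog, 0L)
})
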