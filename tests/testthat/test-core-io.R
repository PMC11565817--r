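# Domain containers and format boundaries: GTF/BED/bedGraph/chain/FASTA/
# junction-table readers and writers, coordinate conventions, validation.

test_that("annotation construction validates exon structure", {
  ann <- mk_ann(tx_rows("t1", list(c(101, 200), c(301, 400))))
  expect_equal(n_transcripts(ann), 1L)
  expect_equal(ann$transcripts$start, 101L)
  expect_equal(ann$transcripts$end, 400L)
  intr <- introns_of(ann)
  expect_equal(intr$intron_start, 201L)
  expect_equal(intr$intron_end, 300L)

  expect_error(mk_ann(tx_rows("t1", list(c(200, 100)))), "end < start")
  expect_error(mk_ann(tx_rows("t1", list(c(100, 200), c(150, 300)))),
               "overlapping or adjacent")
  expect_error(mk_ann(tx_rows("t1", list(c(100, 200), c(201, 300)))),
               "overlapping or adjacent")
  df <- tx_rows("t1", list(c(100, 200)))
  df$strand <- "."
  expect_error(lnc_annotation(df), "stranded")
  expect_error(mk_ann(tx_rows("t1", list(c(100, 9000))),
                      chrom_sizes = c(chr1 = 5000L)),
               "beyond declared")
})

test_that("GTF conversion between 1-based file and internal coordinates", {
  td <- withr::local_tempdir()
  f <- file.path(td, "a.gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    f)
  ann <- read_gtf(f)
  expect_equal(GenomicRanges::start(ann$exons), c(101L, 301L))
  expect_equal(GenomicRanges::end(ann$exons), c(200L, 400L))
  intr <- introns_of(ann)
  expect_equal(c(intr$intron_start, intr$intron_end), c(201L, 300L))

  write_gtf(ann, file.path(td, "b.gtf"))
  lines <- readLines(file.path(td, "b.gtf"))
  exon_lines <- grep("\texon\t", lines, value = TRUE)
  expect_equal(length(exon_lines), 2L)
  expect_match(exon_lines[1], "\t101\t200\t")
})

test_that("GTF accepts the key=value dialect on read", {
  td <- withr::local_tempdir()
  f <- file.path(td, "kv.gff")
  writeLines(c(
    "chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id=g1;transcript_id=t1",
    "chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id=g1;transcript_id=t1"), f)
  ann <- read_gtf(f)
  expect_equal(ann$transcripts$transcript_id, "t1")
  expect_equal(ann$transcripts$n_exons, 2L)
})

test_that("GTF write/read round trip is the identity on annotations", {
  b <- shared_bundle()
  for (ann in list(b$reference_a, b$candidates)) {
    f <- withr::local_tempfile(fileext = ".gtf")
    write_gtf(ann, f)
    r <- read_gtf(f)
    expect_identical(as.data.frame(r$exons), as.data.frame(ann$exons))
    expect_identical(r$transcripts, ann$transcripts)
    expect_identical(r$genes, ann$genes)
  }
})

test_that("BED and bedGraph tracks read with normalized conventions", {
  td <- withr::local_tempdir()
  f <- file.path(td, "t.bed")
  writeLines(c("chr1\t999\t2000\tdELS", "chr2\t10\t20\tPLS"), f)
  tr <- read_track(f, "bed")
  expect_equal(GenomicRanges::start(tr), c(1000L, 11L))
  expect_equal(GenomicRanges::end(tr), c(2000L, 20L))
  expect_equal(S4Vectors::mcols(tr)$label, c("dELS", "PLS"))
  expect_true(all(as.character(GenomicRanges::strand(tr)) == "*"))

  g <- file.path(td, "t.bedGraph")
  writeLines("chr1\t0\t10\t0.5", g)
  bg <- read_track(g, "bedgraph")
  expect_equal(GenomicRanges::width(bg), 10L)
  expect_equal(S4Vectors::mcols(bg)$score, 0.5)
})

test_that("chain parser reconstructs blocks and validates header spans", {
  td <- withr::local_tempdir()
  f <- file.path(td, "a.chain")
  writeLines(c("chain 100 chr1 20000 + 100 200 chr9 30000 + 1100 1200 7",
               "100", ""), f)
  ch <- read_chain(f)[[1]]
  expect_equal(ch$blocks, data.frame(src = 100L, tgt = 1100L, size = 100L))
  expect_equal(ch$id, "7")

  f2 <- file.path(td, "gap.chain")
  writeLines(c("chain 100 chr1 20000 + 100 200 chr9 30000 + 1100 1190 8",
               "50\t10\t0", "40", ""), f2)
  ch2 <- read_chain(f2)[[1]]
  expect_equal(ch2$blocks$src, c(100L, 160L))  # source gap 10
  expect_equal(ch2$blocks$tgt, c(1100L, 1150L)) # target gap 0
  expect_equal(ch2$blocks$size, c(50L, 40L))

  f3 <- file.path(td, "bad.chain")
  writeLines(c("chain 100 chr1 20000 + 100 250 chr9 30000 + 1100 1200 9",
               "100", ""), f3)
  expect_error(read_chain(f3), "9")
})

test_that("chain write/read round trip preserves minus-orientation chains", {
  ch <- mk_chain(rbind(c(100, 300, 50), c(200, 400, 80)),
                 tgt_strand = "-", tgt_size = 2000L, id = "m1")
  f <- withr::local_tempfile(fileext = ".chain")
  write_chain(list(ch), f)
  back <- read_chain(f)[[1]]
  expect_identical(back$blocks, ch$blocks)
  expect_identical(back$tgt_strand, "-")
  expect_identical(back[sort(names(back))], ch[sort(names(ch))])
})

test_that("junction table lookups treat absent junctions as zero", {
  td <- withr::local_tempdir()
  f <- file.path(td, "j.tsv")
  writeLines(c("chr1\t+\t200\t300\t50", "chr2\t-\t10\t90\t7"), f)
  s <- read_junction_support(f)
  # donor 200 (0-based) == intron start 201 (1-based)
  expect_equal(junction_count(s, junction_key("chr1", "+", 201L, 300L)), 50L)
  expect_equal(junction_count(s, junction_key("chr1", "+", 999L, 1100L)), 0L)

  f2 <- file.path(td, "neg.tsv")
  writeLines("chr1\t+\t200\t300\t-1", f2)
  expect_error(read_junction_support(f2), "negative")
})

test_that("every reader emits intervals within declared bounds", {
  b <- shared_bundle()
  td <- withr::local_tempdir()
  write_bundle(b, td)
  sizes <- read_chrom_sizes(file.path(td, "genome_a.sizes"))
  expect_identical(sizes, b$chrom_sizes_a)
  for (f in c("cage.bed", "ccres.bed", "gwas.bed", "smallrna.bed")) {
    tr <- read_track(file.path(td, f), "bed")
    expect_true(all(GenomicRanges::start(tr) >= 1))
    expect_true(all(GenomicRanges::end(tr) <=
                      sizes[as.character(GenomeInfoDb::seqnames(tr))]))
  }
  cons <- read_track(file.path(td, "conservation.bedGraph"), "bedgraph")
  expect_true(all(GenomicRanges::end(cons) <=
                    sizes[as.character(GenomeInfoDb::seqnames(cons))]))
})
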