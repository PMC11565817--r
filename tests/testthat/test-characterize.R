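# Evidence-track evaluation: TSS extraction and support windows, polyA
# motifs, cCRE support/reclassification, TF profiles, GWAS densities and
# profiles, small-RNA hosting.

pt <- function(pos, chrom = "chr1", strand = "+")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos), strand = strand)

iv <- function(s, e, chrom = "chr1", ...)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e), ...)

test_that("TSS extraction is strand-aware and deduplicated", {
  ann <- mk_ann(tx_rows("p", list(c(100, 200), c(301, 500))),
                tx_rows("m", list(c(100, 500)), strand = "-"),
                tx_rows("p2", list(c(100, 250))))
  tss <- extract_tss(ann)
  expect_equal(length(tss), 2L)  # p and p2 share position 100 on +
  plus <- tss[as.character(GenomicRanges::strand(tss)) == "+"]
  minus <- tss[as.character(GenomicRanges::strand(tss)) == "-"]
  expect_equal(GenomicRanges::start(plus), 100L)
  expect_equal(GenomicRanges::start(minus), 500L)  # last covered base
  expect_equal(S4Vectors::mcols(plus)$n_transcripts, 2L)
})

test_that("TSS support flips exactly between offsets 50 and 51", {
  tss <- pt(10000)
  covering <- iv(9990, 10010)
  at50 <- iv(10050, 10080)   # nearest edge 50 positions away
  at51 <- iv(10051, 10080)
  expect_true(tss_support(tss, list(x = covering))$supported[1, "x"])
  expect_true(tss_support(tss, list(x = at50))$supported[1, "x"])
  expect_false(tss_support(tss, list(x = at51))$supported[1, "x"])
  # upstream side as well
  expect_true(tss_support(tss, list(x = iv(9900, 9950)))$supported[1, "x"])
  expect_false(tss_support(tss, list(x = iv(9900, 9949)))$supported[1, "x"])
  # the "any" column is the union over tracks
  s <- tss_support(tss, list(a = at51, b = at50))
  expect_true(s$supported[1, "any"])
  expect_equal(s$summary$fraction[s$summary$track == "a"], 0)
})

test_that("polyA support honours the 10-50 bp upstream window", {
  mk_genome <- function(offset, strand = "+", motif = "AATAAA") {
    s <- strsplit(paste(rep("C", 3000), collapse = ""), "")[[1]]
    if (strand == "+") {
      p <- 2000 - offset
      s[p:(p + 5)] <- strsplit(motif, "")[[1]]
    } else {
      p <- 1000 + offset
      s[(p - 5):p] <- strsplit(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif))), "")[[1]]
    }
    Biostrings::DNAStringSet(c(chr1 = paste(s, collapse = "")))
  }
  ann_p <- mk_ann(tx_rows("t", list(c(1000, 2000))))
  ann_m <- mk_ann(tx_rows("t", list(c(1000, 2000)), strand = "-"))
  for (off in c(10, 30, 50))
    expect_true(polya_support(ann_p, mk_genome(off))$supported[["t"]],
                label = sprintf("plus offset %d", off))
  for (off in c(5, 55))
    expect_false(polya_support(ann_p, mk_genome(off))$supported[["t"]],
                 label = sprintf("plus offset %d", off))
  # minus strand: motif planted on the sense (reverse-complement) strand
  expect_true(polya_support(ann_m, mk_genome(30, "-"))$supported[["t"]])
  expect_false(polya_support(ann_m, mk_genome(5, "-"))$supported[["t"]])
  expect_true(polya_support(ann_m, mk_genome(30, "-", "ATTAAA"))$supported[["t"]])
  # a plus-strand motif does not support a minus-strand transcript
  expect_false(polya_support(ann_m, mk_genome(30, "+"))$supported[["t"]])
})

test_that("cCRE support uses a strict 2 kb center distance", {
  tss <- pt(10000)
  mk_ccre <- function(center, label)
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(center - 100, center + 100),
                           label = label)
  # center-of-interval arithmetic: [c-100, c+100] has center c
  expect_true(ccre_support(tss, mk_ccre(11999, "dELS"))$supported[1, "dELS"])
  expect_false(ccre_support(tss, mk_ccre(12000, "dELS"))$supported[1, "dELS"])
  both <- c(mk_ccre(10100, "PLS"), mk_ccre(11500, "dELS"))
  s <- ccre_support(tss, both)
  expect_true(all(s$supported[1, c("PLS", "dELS", "any")]))
  expect_equal(s$summary$n_supported[s$summary$track == "any"], 1L)
  expect_error(ccre_support(tss, mk_ccre(10100, "bogus")), "unknown cCRE")
})

test_that("cCRE reclassification performs only the two permitted moves", {
  tss <- pt(10000)
  ccres <- c(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(11400, 11600),
                           label = "dELS"),        # center 1500 away -> pELS
    GenomicRanges::GRanges("chr1", IRanges::IRanges(12400, 12600),
                           label = "dELS"),        # center 2500 away -> stays
    GenomicRanges::GRanges("chr1", IRanges::IRanges(10050, 10250),
                           label = "CA-H3K4me3"),  # center 150 away -> PLS
    GenomicRanges::GRanges("chr1", IRanges::IRanges(10050, 10250),
                           label = "PLS"))
  r <- reclassify_ccres(ccres, tss)
  expect_equal(S4Vectors::mcols(r$ccres)$label,
               c("pELS", "dELS", "PLS", "PLS"))
  expect_equal(sum(r$transitions$count), 4L)
  moved <- r$transitions[r$transitions$from != r$transitions$to, ]
  expect_setequal(paste(moved$from, moved$to),
                  c("dELS pELS", "CA-H3K4me3 PLS"))
})

test_that("reclassification algebra holds on random records", {
  set.seed(99)
  n <- 2000L
  centers <- sample.int(5e5, n)
  lab <- sample(c("PLS", "pELS", "dELS", "CA-H3K4me3", "CA-CTCF", "CA",
                  "TF", "CA-TF"), n, replace = TRUE)
  ccres <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(centers - 50, centers + 50),
                                  label = lab)
  tss <- pt(sort(sample.int(5e5, 300)))
  r1 <- reclassify_ccres(ccres, tss)
  expect_equal(length(r1$ccres), n)                      # count conserved
  moved <- r1$transitions[r1$transitions$from != r1$transitions$to, ]
  expect_true(all(paste(moved$from, moved$to) %in%
                    c("dELS pELS", "CA-H3K4me3 PLS")))
  r2 <- reclassify_ccres(r1$ccres, tss)                  # idempotence
  expect_identical(S4Vectors::mcols(r2$ccres)$label,
                   S4Vectors::mcols(r1$ccres)$label)
})

test_that("TF window coverage matches exact arithmetic on one peak", {
  tss <- pt(100000)
  peak <- iv(100000 - 250, 100000 + 249)   # exactly [TSS-250, TSS+250)
  prof <- tf_coverage_profile(tss, list(TF1 = peak))
  df <- prof$profile
  expect_equal(nrow(df), 20L)
  expect_equal(df$mean_coverage[df$offset_start == -500], 0.5)
  expect_equal(df$mean_coverage[df$offset_start == 0], 0.5)
  expect_equal(sum(df$mean_coverage), 1.0)   # all other windows zero
  expect_equal(prof$tf_per_tss, 1L)
  # oriented flip: the same construction on a minus-strand TSS
  prof_m <- tf_coverage_profile(pt(100000, strand = "-"),
                                list(TF1 = iv(100000 - 249, 100000 + 250)))
  expect_equal(prof_m$profile$mean_coverage[prof_m$profile$offset_start == -500],
               0.5)
  expect_error(tf_coverage_profile(tss, list(TF1 = peak), window = 333L),
               "divide")
  empty <- tf_coverage_profile(tss, list(TF1 = GenomicRanges::GRanges()))
  expect_true(all(empty$profile$mean_coverage == 0))
  expect_equal(empty$tf_per_tss, 0L)
})

test_that("GWAS densities are exact on constructed regions", {
  # single 50 kb gene with 5 hits in its body -> 10 per 100 kb
  ann <- mk_ann(tx_rows("g", list(c(10001, 60000))),
                chrom_sizes = c(chr1 = 200000L))
  hits <- pt(c(15000, 20000, 30000, 42000, 55000))
  expect_equal(gwas_density(ann, hits, "gene_body")$density, 10)
  expect_error(gwas_density(ann, hits[0], "gene_body"), NA)
  # conservation: body + complement recombine to the global density
  b <- shared_bundle()
  acc <- shared_demo()$tagene$accepted
  body <- gwas_density(acc, b$gwas, "gene_body")
  comp <- gwas_density(acc, b$gwas, "complement",
                       chrom_sizes = b$chrom_sizes_a)
  total_bp <- sum(b$chrom_sizes_a)
  global <- length(b$gwas) / total_bp * 1e5
  recombined <- (body$density * body$region_bp +
                   comp$density * comp$region_bp) / total_bp
  expect_equal(recombined, global, tolerance = 1e-12)
  expect_equal(body$region_bp + comp$region_bp, total_bp)
})

test_that("GWAS profile localizes boundary-planted hits", {
  ann <- mk_ann(tx_rows("g", list(c(50001, 70000))),
                chrom_sizes = c(chr1 = 200000L))
  # hits hugging both gene boundaries
  hits <- pt(c(50001, 50050, 50120, 69950, 69990, 70000))
  prof <- gwas_profile(ann, hits, flank = 15000L, n_bins = 10L)
  expect_equal(sum(prof$n_hits), 6)
  body <- prof[prof$zone == "body", ]
  top2 <- body$bin[order(-body$density)][1:2]
  expect_setequal(top2, c(min(body$bin), max(body$bin)))
  none <- gwas_profile(ann, hits[0], flank = 15000L, n_bins = 10L)
  expect_true(all(none$density == 0))
})

test_that("small RNAs are hosted by same-strand containing spans only", {
  ann <- mk_ann(tx_rows("host", list(c(1000, 1200), c(5001, 5200))))
  sr <- c(iv(2000, 2021, strand = "+", label = "in_intron"),
          iv(2000, 2021, strand = "-", label = "antisense"),
          iv(5190, 5211, strand = "+", label = "overhang"),
          iv(9000, 9021, strand = "+", label = "outside"))
  h <- smallrna_hosts(sr, ann)
  expect_equal(setNames(h$table$hosted, h$table$small_rna),
               c(in_intron = TRUE, antisense = FALSE, overhang = FALSE,
                 outside = FALSE))
  expect_equal(h$fraction_hosted, 0.25)
  expect_error(smallrna_hosts(iv(10, 30), ann), "stranded")

  b <- shared_bundle()
  hosts <- smallrna_hosts(b$small_rnas, b$reference_a)
  tr <- merge(hosts$table, b$truth$small_rnas,
              by.x = "small_rna", by.y = "label")
  expect_identical(tr$hosted, tr$fate == "hosted")
})

test_that("side-by-side comparison separates real sets from decoys", {
  d <- shared_demo()
  tab <- d$characterization
  dec <- tab[tab$set == "decoy", ]
  real <- tab[tab$set != "decoy", ]
  metrics <- c("tss_support_any", "ccre_support_any", "polya_fraction",
               "tf_frac_tss_covered", "tf_mean_per_tss", "gwas_body_density")
  for (m in metrics)
    expect_true(all(real[[m]] >= dec[[m]]), label = m)
  fracs <- unlist(tab[c("tss_support_any", "ccre_support_any",
                        "polya_fraction", "tf_frac_tss_covered")])
  expect_true(all(fracs >= 0 & fracs <= 1))
})
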