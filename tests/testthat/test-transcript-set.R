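# Intron-chain keys, cross-sample merging, novelty classification, sample
# sharing and target yield.

test_that("intron-chain keys ignore transcript termini", {
  ann <- mk_ann(
    tx_rows("a", list(c(101, 200), c(301, 400))),
    tx_rows("b", list(c(151, 200), c(301, 450))),
    tx_rows("c", list(c(1, 10), c(21, 30), c(41, 50)), chrom = "chr2"),
    tx_rows("m", list(c(101, 400)), strand = "-"))
  k <- intron_chain_keys(ann)
  expect_identical(k[["a"]], k[["b"]])
  expect_match(k[["a"]], "201-300")
  expect_match(k[["c"]], "11-20,31-40")
  expect_match(k[["m"]], "mono")
})

test_that("merging uses extremal termini and keeps provenance", {
  ann <- mk_ann(
    tx_rows("a", list(c(100, 200), c(301, 1000))),
    tx_rows("b", list(c(120, 200), c(301, 980))))
  m <- merge_models(ann)
  expect_equal(n_transcripts(m$annotation), 1L)
  expect_equal(m$annotation$transcripts$start, 100L)
  expect_equal(m$annotation$transcripts$end, 1000L)
  expect_setequal(m$members$member_id, c("a", "b"))
  # internal junction preserved
  intr <- introns_of(m$annotation)
  expect_equal(c(intr$intron_start, intr$intron_end), c(201L, 300L))
})

test_that("distinct chains stay distinct and detections follow samples", {
  ann <- mk_ann(
    tx_rows("a", list(c(100, 200), c(301, 400))),
    tx_rows("b", list(c(100, 200), c(351, 400))),
    tx_rows("c", list(c(1000, 1100), c(1201, 1300))))
  samples <- data.frame(transcript_id = c("a", "b", "c"),
                        sample_id = c("s1", "s2", "s3"))
  m <- merge_models(ann, samples)
  expect_equal(n_transcripts(m$annotation), 3L)
  expect_equal(nrow(m$sample_matrix), 3L)
  expect_true(all(table(m$sample_matrix$merged_id) == 1L))
})

test_that("monoexonic models merge by >=50% reciprocal span overlap", {
  ann <- mk_ann(
    tx_rows("a", list(c(100, 1000))),
    tx_rows("b", list(c(150, 1050))),    # ~94% reciprocal: merges
    tx_rows("c", list(c(900, 2700))),    # small reciprocal overlap: not
    tx_rows("d", list(c(100, 1000)), strand = "-"))  # other strand: not
  m <- merge_models(ann)
  expect_equal(n_transcripts(m$annotation), 3L)
})

test_that("merged set equals the O(n^2) pairwise grouping oracle", {
  for (seed in c(1, 2)) {
    ann <- random_models(200, seed = seed)
    m <- merge_models(ann)
    got <- canon_groups(split(m$members$member_id, m$members$merged_id))
    want <- canon_groups(merge_oracle_groups(ann))
    expect_identical(got, want)
  }
})

test_that("merging is idempotent and never grows the set", {
  ann <- random_models(150, seed = 3)
  m1 <- merge_models(ann)
  expect_lte(n_transcripts(m1$annotation), n_transcripts(ann))
  m2 <- merge_models(m1$annotation)
  expect_equal(n_transcripts(m2$annotation), n_transcripts(m1$annotation))
  expect_identical(as.data.frame(GenomicRanges::granges(m2$annotation$exons)),
                   as.data.frame(GenomicRanges::granges(m1$annotation$exons)))
})

test_that("novelty categories follow the documented precedence", {
  reference <- mk_ann(
    tx_rows("ref1", list(c(1000, 1200), c(2001, 2300)), gene_id = "gL",
            biotype = "lncRNA"),
    tx_rows("ref2", list(c(10000, 10500), c(12001, 12500)), gene_id = "gP",
            strand = "-", biotype = "protein_coding"))
  models <- mk_ann(
    tx_rows("known", list(c(1100, 1200), c(2001, 2250))),
    tx_rows("novel", list(c(1100, 1300), c(1601, 1700))),
    tx_rows("intronic", list(c(10600, 10700), c(11001, 11100)), strand = "-"),
    tx_rows("anti", list(c(10400, 10600), c(11501, 11600))),
    tx_rows("inter", list(c(50000, 50200), c(50501, 50700))))
  nv <- classify_novelty(models, reference)
  got <- setNames(nv$category, nv$model_id)
  expect_equal(got[["known"]], "known")
  expect_equal(got[["novel"]], "novel_transcript_known_gene")
  expect_equal(got[["intronic"]], "intronic_overlap")
  expect_equal(got[["anti"]], "antisense_overlap")
  expect_equal(got[["inter"]], "novel_gene_intergenic")
  expect_equal(nv$matched_ids[nv$model_id == "novel"], "gL")
})

test_that("novelty is a partition on random model sets", {
  b <- shared_bundle()
  nv <- classify_novelty(b$candidates, b$reference_a)
  expect_equal(nrow(nv), n_transcripts(b$candidates))
  expect_true(all(nv$category %in%
                    c("known", "novel_transcript_known_gene",
                      "intronic_overlap", "antisense_overlap",
                      "novel_gene_intergenic")))
  expect_false(any(duplicated(nv$model_id)))
  # planted truth matches exactly
  tr <- merge(nv, b$truth$models, by = "model_id")
  expect_identical(tr$category, tr$novelty)
})

test_that("sample sharing recovers planted counts exactly", {
  sm <- data.frame(
    merged_id = c(sprintf("m%02d", 1:10), "m01", "m02", "m02"),
    sample_id = c(rep("adult_brain", 10), "embryo_brain", "adult_liver",
                  "embryo_liver"))
  meta <- data.frame(sample_id = c("adult_brain", "embryo_brain",
                                   "adult_liver", "embryo_liver"),
                     tissue = c("brain", "brain", "liver", "liver"),
                     stage = c("adult", "embryo", "adult", "embryo"),
                     capture = c("post", "post", "pre", "post"))
  sh <- sample_sharing(sm, meta)
  expect_equal(sh$summary$frac_unique_sample, 0.8)  # 8 of 10 in one sample
  per <- setNames(sh$per_model$stage_class, sh$per_model$merged_id)
  expect_equal(per[["m01"]], "both")
  expect_equal(per[["m02"]], "both")
  expect_equal(per[["m03"]], "adult")
  cap <- setNames(sh$per_model$capture_class, sh$per_model$merged_id)
  expect_equal(cap[["m02"]], "both")

  d <- shared_demo()
  joined <- merge(merge(d$merged$members, d$sharing$per_model,
                        by = "merged_id"),
                  d$bundle$truth$unique_sample,
                  by.x = "member_id", by.y = "model_id")
  expect_identical(joined$n_samples == 1L, joined$unique)
})

test_that("target yield counts strand-aware exon overlap", {
  models <- mk_ann(tx_rows("t1", list(c(1000, 1200), c(2001, 2200))))
  targets <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1100, 1500, 5000, 8000),
                             c(1150, 1600, 5100, 8100)),
    strand = c("*", "*", "*", "*"),
    label = c("a", "a", "b", "b"))
  y <- target_yield(targets, models)
  expect_equal(y$fraction, 0.25)
  expect_equal(y$per_class$fraction[y$per_class$class == "a"], 0.5)
  expect_equal(y$per_class$fraction[y$per_class$class == "b"], 0)

  # stranded target with only antisense overlap is not detected;
  # an intron-only overlap is not detected either
  targets2 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1100, 1100, 1300), c(1150, 1150, 1400)),
    strand = c("+", "-", "+"))
  y2 <- target_yield(targets2, models)
  expect_identical(y2$detected, c(TRUE, FALSE, FALSE))
})
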