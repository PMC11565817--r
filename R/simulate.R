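# Seeded synthetic-data generator. Produces every input the pipeline
# consumes -- two genomes with annotations, candidate models with planted
# violation/novelty classes, junction support with planted weak introns,
# evidence tracks with planted TSS-proximal enrichment, a conservation
# track with neutral background and planted conserved transcripts, and
# chain alignments with planted 1:1 / 1:2 / lost gene fates -- together
# with the ground truth needed to check each stage's recovery.

#' Configuration of the synthetic bundle
#'
#' Defaults describe a desk-scale genome pair (two chromosomes, ~0.7 Mb)
#' with realistic lncRNA-annotation statistics: log-normal exon/intron
#' lengths, overdispersed junction counts, CAGE jitter around TSSs,
#' TSS-proximity-stratified cCRE classes, TF peaks enriched at TSSs, GWAS
#' hits at a genome-wide background rate with gene-body enrichment, and a
#' zero-mean conservation background with strongly conserved planted exons.
#'
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @param chrom_sizes Named sizes of genome A chromosomes.
#' @param n_pc,n_lnc,n_pseudo Reference gene counts per biotype.
#' @param exon_mean_log,exon_sd_log,intron_mean_log,intron_sd_log
#'   Log-normal location/spread of exon and intron lengths (bp).
#' @param mean_exons Mean additional exon count (1 + Poisson).
#' @param n_candidates Candidate CLS-like models.
#' @param frac_known,frac_novel,frac_intergenic,frac_antisense,frac_pseudo,frac_low_support
#'   Planted candidate class fractions (sum <= 1; remainder goes to
#'   `known`).
#' @param junction_mu,junction_size Negative-binomial mean/dispersion of
#'   supported junction counts (shifted to >= `min_reads`).
#' @param min_reads Support threshold the planted classes straddle; planted
#'   weak introns draw uniformly from 1..`min_reads - 1`.
#' @param cage_jitter_sd CAGE cluster jitter around TSSs (bp).
#' @param n_background_clusters Background CAGE clusters.
#' @param n_tf,tf_peaks_bg,tf_tss_prob TF track count, background peaks per
#'   TF, and per-TSS probability of a TSS-centered peak.
#' @param gwas_rate,gwas_gene_enrich GWAS background rate (hits/bp) and
#'   gene-body enrichment multiplier.
#' @param cons_sd,cons_conserved_mean,frac_conserved Conservation
#'   background sd (mean 0), planted conserved exon mean, and fraction of
#'   lncRNA transcripts planted conserved.
#' @param cons_tile Tile width (bp) of the conservation track.
#' @param frac_polya Fraction of transcripts with a planted polyA motif
#'   30 bp upstream of the 3' end (motif-free elsewhere by scrubbing).
#' @param frac_ortho_lost,frac_ortho_dup Fractions of lncRNA genes deleted
#'   in genome B / duplicated in genome B (1:2 orthology).
#' @param frac_unique_sample Fraction of candidates detected in exactly one
#'   sample.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chrom_sizes = c(chr1 = 400000L, chr2 = 300000L),
                       n_pc = 22L, n_lnc = 30L, n_pseudo = 6L,
                       exon_mean_log = log(150), exon_sd_log = 0.4,
                       intron_mean_log = log(700), intron_sd_log = 0.5,
                       mean_exons = 3,
                       n_candidates = 60L,
                       frac_known = 0.25, frac_novel = 0.2,
                       frac_intergenic = 0.2, frac_antisense = 0.1,
                       frac_pseudo = 0.1, frac_low_support = 0.15,
                       junction_mu = 300, junction_size = 2,
                       min_reads = 50L,
                       cage_jitter_sd = 10, n_background_clusters = 120L,
                       n_tf = 5L, tf_peaks_bg = 150L, tf_tss_prob = 0.7,
                       gwas_rate = 1e-4, gwas_gene_enrich = 2,
                       cons_sd = 0.3, cons_conserved_mean = 3.0,
                       frac_conserved = 0.3, cons_tile = 10L,
                       frac_polya = 0.6,
                       frac_ortho_lost = 0.15, frac_ortho_dup = 0.15,
                       frac_unique_sample = 0.8) {
  if (missing(seed)) stop("seed is mandatory")
  fr <- c(frac_known, frac_novel, frac_intergenic, frac_antisense,
          frac_pseudo, frac_low_support)
  if (any(fr < 0) || sum(fr) > 1 + 1e-9)
    stop("candidate class fractions must be >= 0 and sum <= 1")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# random multi-exon structure: exon starts/ends relative to a start of 0
sim_structure <- function(cfg, min_exons = 1L) {
  n_ex <- max(min_exons, 1L + rpois(1, cfg$mean_exons - 1))
  elen <- pmax(30L, round(rlnorm(n_ex, cfg$exon_mean_log, cfg$exon_sd_log)))
  ilen <- if (n_ex > 1L)
    pmax(60L, round(rlnorm(n_ex - 1L, cfg$intron_mean_log, cfg$intron_sd_log)))
  else integer(0)
  starts <- cumsum(c(0L, head(elen, -1L) + ilen))
  list(starts = as.integer(starts), ends = as.integer(starts + elen - 1L))
}

exon_rows <- function(chrom, pos, strand, struct, tx_id, gene_id, biotype) {
  data.frame(chrom = chrom, start = pos + struct$starts,
             end = pos + struct$ends, strand = strand,
             transcript_id = tx_id, gene_id = gene_id, biotype = biotype,
             stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate the full synthetic input bundle
#'
#' See [sim_config()] for the generative model. Identical seeds yield
#' byte-identical bundles when written with [write_bundle()].
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_bundle`: genomes (`genome_a`, `genome_b`
#'   as `DNAStringSet`, plus `chrom_sizes_a/b`), annotations
#'   (`reference_a`, `reference_b`, `candidates`), `candidate_samples` and
#'   `sample_meta`, `junctions` (support table), evidence tracks (`cage`,
#'   `procap`, `ccres`, `tf_peaks`, `gwas`, `small_rnas`, `targets`),
#'   `conservation` (score track), `chains_ab`/`chains_ba`, and `truth`
#'   (per-entity planted labels).
#' @export
simulate_bundle <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  set.seed(cfg$seed)
  sizes <- cfg$chrom_sizes
  chroms <- names(sizes)

  ## ---- reference gene placement on genome A ----
  n_genes <- cfg$n_pc + cfg$n_lnc + cfg$n_pseudo
  biotypes <- sample(rep(c("protein_coding", "lncRNA", "pseudogene"),
                         c(cfg$n_pc, cfg$n_lnc, cfg$n_pseudo)))
  ref_rows <- list()
  gene_tbl <- list()
  margin <- 16000L   # clear of profile flanks at chromosome ends
  per_chrom <- split(seq_len(n_genes),
                     rep(chroms, length.out = n_genes))
  for (ch in chroms) {
    cursor <- margin
    for (gi in per_chrom[[ch]]) {
      bt <- biotypes[gi]
      strand <- sample(c("+", "-"), 1L)
      st <- if (bt == "pseudogene")
        list(starts = 0L, ends = 2000L + sample.int(2000L, 1L))
      else sim_structure(cfg, min_exons = if (bt == "lncRNA") 2L else 1L)
      span <- st$ends[length(st$ends)] + 1L
      gap <- 3000L + sample.int(4000L, 1L)
      pos <- cursor + gap
      if (pos + span + margin > sizes[[ch]])
        stop("infeasible packing: genes exceed capacity of ", ch)
      gid <- sprintf("G%03d", gi)
      tid <- sprintf("G%03d.t1", gi)
      ref_rows[[gi]] <- exon_rows(ch, pos, strand, st, tid, gid, bt)
      gene_tbl[[gi]] <- data.frame(gene_id = gid, tx = tid, biotype = bt,
                                   chrom = ch, strand = strand,
                                   start = pos, end = pos + span - 1L,
                                   stringsAsFactors = FALSE)
      cursor <- pos + span
    }
  }
  gene_tbl <- do.call(rbind, gene_tbl)
  reference_a <- lnc_annotation(do.call(rbind, ref_rows), chrom_sizes = sizes)

  gene_spans_gr <- gene_spans(reference_a)
  place_intergenic <- function(ch, span_len, buffer = 1500L) {
    for (a in 1:500) {
      pos <- margin + sample.int(sizes[[ch]] - span_len - 2L * margin, 1L)
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos - buffer,
                                                          pos + span_len + buffer))
      if (!IRanges::overlapsAny(cand, gene_spans_gr,
                                      ignore.strand = TRUE))
        return(pos)
    }
    stop("infeasible packing: no intergenic space for span ", span_len)
  }

  ## ---- candidate models with planted classes ----
  nc <- cfg$n_candidates
  n_cls <- c(novel = round(cfg$frac_novel * nc),
             intergenic = round(cfg$frac_intergenic * nc),
             antisense = round(cfg$frac_antisense * nc),
             pseudo = round(cfg$frac_pseudo * nc),
             low_support = round(cfg$frac_low_support * nc))
  n_cls <- c(known = nc - sum(n_cls), n_cls)
  lnc_tbl <- gene_tbl[gene_tbl$biotype == "lncRNA", ]
  pc_tbl <- gene_tbl[gene_tbl$biotype == "protein_coding", ]
  ps_tbl <- gene_tbl[gene_tbl$biotype == "pseudogene", ]
  ref_ex <- reference_a$exons
  ref_ex_tx <- S4Vectors::mcols(ref_ex)$transcript_id

  cand_rows <- list(); truth_models <- list(); low_introns <- list()
  k <- 0L
  new_id <- function() { k <<- k + 1L; sprintf("C%03d", k) }
  jitter_pos <- function(x, lo, hi) max(lo, min(hi, x + sample(-80:80, 1L)))

  copy_ref_chain <- function(src_tx, id, skip_exon = FALSE) {
    e <- ref_ex[ref_ex_tx == src_tx]
    e <- e[order(GenomicRanges::start(e))]
    s <- GenomicRanges::start(e); en <- GenomicRanges::end(e)
    if (skip_exon && length(s) >= 3L) {
      drop <- 1L + sample.int(length(s) - 2L, 1L)
      s <- s[-drop]; en <- en[-drop]
    }
    # jitter termini without crossing the first/last junction
    s[1] <- jitter_pos(s[1], 1L, en[1] - 20L)
    en[length(en)] <- jitter_pos(en[length(en)], s[length(s)] + 20L,
                                 sizes[[as.character(GenomeInfoDb::seqnames(e))[1]]])
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(e))[1],
               start = s, end = en,
               strand = as.character(GenomicRanges::strand(e))[1],
               transcript_id = id, gene_id = id, biotype = "other",
               stringsAsFactors = FALSE)
  }

  # distinct sources where the pool allows, so candidate chains are unique
  # and the merged set maps 1:1 onto candidates
  pick_pool <- function(pool, n) sample(pool, n, replace = n > length(pool))
  spliced_lnc <- lnc_tbl$tx
  pick_known <- pick_pool(spliced_lnc, n_cls[["known"]])
  for (src in pick_known) {
    id <- new_id()
    cand_rows[[id]] <- copy_ref_chain(src, id)
    truth_models[[id]] <- c("known", "none")
  }
  multi3 <- lnc_tbl$tx[reference_a$transcripts$n_exons[
    match(lnc_tbl$tx, reference_a$transcripts$transcript_id)] >= 3L]
  pick_novel <- pick_pool(multi3, n_cls[["novel"]])
  for (src in pick_novel) {
    id <- new_id()
    cand_rows[[id]] <- copy_ref_chain(src, id, skip_exon = TRUE)
    truth_models[[id]] <- c("novel_transcript_known_gene", "none")
  }
  make_intergenic <- function(id, filter_label) {
    ch <- sample(chroms, 1L)
    st <- sim_structure(cfg, min_exons = 2L)
    span <- st$ends[length(st$ends)] + 1L
    pos <- place_intergenic(ch, span)
    cand_rows[[id]] <<- exon_rows(ch, pos, sample(c("+", "-"), 1L), st,
                                  id, id, "other")
    truth_models[[id]] <<- c("novel_gene_intergenic", filter_label)
  }
  for (i in seq_len(n_cls[["intergenic"]])) make_intergenic(new_id(), "none")
  for (i in seq_len(n_cls[["low_support"]])) {
    id <- new_id()
    make_intergenic(id, "low_junction_support")
    r <- cand_rows[[id]]
    low_introns[[id]] <- c(r$chrom[1], r$strand[1],
                           r$end[1] + 1L, r$start[2] - 1L)
  }
  pick_pc <- pc_tbl[pick_pool(seq_len(nrow(pc_tbl)), n_cls[["antisense"]]), ]
  for (i in seq_len(nrow(pick_pc))) {
    id <- new_id()
    g <- pick_pc[i, ]
    e <- ref_ex[S4Vectors::mcols(ref_ex)$gene_id == g$gene_id]
    e1 <- e[order(GenomicRanges::start(e))][1]
    # two-exon model on the opposite strand, first exon overlapping e1
    a1 <- GenomicRanges::start(e1) - 40L
    b1 <- GenomicRanges::start(e1) + 60L
    a2 <- b1 + 200L; b2 <- a2 + 120L
    cand_rows[[id]] <- data.frame(
      chrom = g$chrom, start = c(a1, a2), end = c(b1, b2),
      strand = if (g$strand == "+") "-" else "+",
      transcript_id = id, gene_id = id, biotype = "other",
      stringsAsFactors = FALSE)
    truth_models[[id]] <- c("antisense_overlap", "antisense_pc")
  }
  pick_ps <- ps_tbl[pick_pool(seq_len(nrow(ps_tbl)), n_cls[["pseudo"]]), ]
  for (i in seq_len(nrow(pick_ps))) {
    id <- new_id()
    g <- pick_ps[i, ]
    a1 <- g$start + 100L; b1 <- a1 + 150L
    a2 <- b1 + 200L; b2 <- min(a2 + 150L, g$end - 50L)
    cand_rows[[id]] <- data.frame(
      chrom = g$chrom, start = c(a1, a2), end = c(b1, b2),
      strand = g$strand, transcript_id = id, gene_id = id,
      biotype = "other", stringsAsFactors = FALSE)
    truth_models[[id]] <- c("novel_transcript_known_gene",
                            "pseudogene_contained")
  }
  candidates <- lnc_annotation(do.call(rbind, cand_rows),
                               chrom_sizes = sizes)
  truth_models <- data.frame(
    model_id = names(truth_models),
    novelty = vapply(truth_models, `[`, "", 1L),
    filter_violation = vapply(truth_models, `[`, "", 2L),
    stringsAsFactors = FALSE, row.names = NULL)

  ## ---- junction support ----
  intr <- rbind(introns_of(reference_a), introns_of(candidates))
  keys <- unique(junction_key(intr$chrom, intr$strand, intr$intron_start,
                              intr$intron_end))
  counts <- cfg$min_reads +
    rnbinom(length(keys), mu = cfg$junction_mu, size = cfg$junction_size)
  support <- setNames(as.integer(counts), keys)
  for (li in low_introns) {
    kk <- junction_key(li[1], li[2], as.integer(li[3]), as.integer(li[4]))
    support[kk] <- sample.int(cfg$min_reads - 1L, 1L)
  }
  class(support) <- "junction_support"

  ## ---- sample assignment ----
  sample_meta <- expand.grid(tissue = c("brain", "liver"),
                             stage = c("adult", "embryo"),
                             capture = c("pre", "post"),
                             stringsAsFactors = FALSE)
  sample_meta$sample_id <- with(sample_meta,
                                paste(stage, tissue, capture, sep = "_"))
  n_samp <- nrow(sample_meta)
  uniq <- runif(nc) < cfg$frac_unique_sample
  cand_samples <- do.call(rbind, lapply(seq_len(nc), function(i) {
    k_det <- if (uniq[i]) 1L else 1L + sample.int(2L, 1L)
    data.frame(transcript_id = truth_models$model_id[i],
               sample_id = sample(sample_meta$sample_id, k_det),
               stringsAsFactors = FALSE)
  }))

  ## ---- TSS-linked evidence tracks ----
  all_tss <- extract_tss(lnc_annotation(
    rbind(do.call(rbind, ref_rows), do.call(rbind, cand_rows)),
    chrom_sizes = sizes))
  tss_pos <- GenomicRanges::start(all_tss)
  tss_chrom <- as.character(GenomeInfoDb::seqnames(all_tss))
  n_tss <- length(all_tss)

  mk_clusters <- function(prob, width = 20L) {
    keep <- runif(n_tss) < prob
    centers <- tss_pos[keep] + round(rnorm(sum(keep), 0, cfg$cage_jitter_sd))
    real <- GenomicRanges::GRanges(tss_chrom[keep],
                                   IRanges::IRanges(pmax(1L, centers - width %/% 2L),
                                                    centers + width %/% 2L))
    bg_ch <- sample(chroms, cfg$n_background_clusters, replace = TRUE)
    bg_pos <- vapply(bg_ch, function(ch)
      sample.int(sizes[[ch]] - 100L, 1L) + 50L, integer(1))
    bg <- GenomicRanges::GRanges(bg_ch, IRanges::IRanges(bg_pos, bg_pos + width))
    GenomicRanges::sort(c(real, bg), ignore.strand = TRUE)
  }
  cage <- mk_clusters(0.8)
  procap <- mk_clusters(0.5)

  ## cCREs stratified by TSS proximity, plus planted misclassified records
  ccre_list <- list()
  add_ccre <- function(ch, center, label, half = 100L)
    ccre_list[[length(ccre_list) + 1L]] <<- data.frame(
      chrom = ch, start = pmax(1L, center - half), end = center + half,
      label = label, stringsAsFactors = FALSE)
  for (i in seq_len(n_tss)) {
    r <- runif(4)
    if (r[1] < 0.7) add_ccre(tss_chrom[i], tss_pos[i] + sample(-150:150, 1L), "PLS")
    if (r[2] < 0.5) add_ccre(tss_chrom[i], tss_pos[i] +
                               sample(c(-1, 1), 1L) * sample(300:1500, 1L), "pELS")
    if (r[3] < 0.25) add_ccre(tss_chrom[i], tss_pos[i] + sample(-150:150, 1L),
                              "CA-H3K4me3")      # to be reclassified PLS
    if (r[4] < 0.4) add_ccre(tss_chrom[i], tss_pos[i] +
                               sample(c(-1, 1), 1L) * sample(300:1900, 1L),
                             "dELS")             # to be reclassified pELS
  }
  tss_point <- GenomicRanges::GRanges(tss_chrom,
                                      IRanges::IRanges(tss_pos, tss_pos))
  for (lab in c("dELS", "CA-CTCF", "CA", "TF", "CA-TF")) {
    n_bg <- if (lab == "dELS") 40L else 10L
    placed <- 0L
    while (placed < n_bg) {
      ch <- sample(chroms, 1L)
      center <- sample.int(sizes[[ch]] - 4000L, 1L) + 2000L
      p <- GenomicRanges::GRanges(ch, IRanges::IRanges(center, center))
      d <- point_edge_distance(p, tss_point)
      if (d >= 2200) {    # stays distal under reclassification
        add_ccre(ch, center, lab)
        placed <- placed + 1L
      }
    }
  }
  ccres_df <- do.call(rbind, ccre_list)
  ccres <- GenomicRanges::sort(GenomicRanges::GRanges(
    ccres_df$chrom, IRanges::IRanges(ccres_df$start, ccres_df$end),
    label = ccres_df$label), ignore.strand = TRUE)

  ## TF peaks: uniform background + TSS-centered peaks
  tf_peaks <- setNames(lapply(seq_len(cfg$n_tf), function(t) {
    ch <- sample(chroms, cfg$tf_peaks_bg, replace = TRUE)
    pos <- vapply(ch, function(c2)
      sample.int(sizes[[c2]] - 400L, 1L) + 100L, integer(1))
    bg <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos, pos + 199L))
    keep <- runif(n_tss) < cfg$tf_tss_prob
    at_tss <- GenomicRanges::GRanges(
      tss_chrom[keep],
      IRanges::IRanges(pmax(1L, tss_pos[keep] - 100L), tss_pos[keep] + 100L))
    GenomicRanges::sort(c(bg, at_tss), ignore.strand = TRUE)
  }), sprintf("TF%02d", seq_len(cfg$n_tf)))

  ## GWAS hits: Poisson background + gene-body extra hits
  gwas_pos <- list()
  for (ch in chroms) {
    n_bg <- rpois(1, sizes[[ch]] * cfg$gwas_rate)
    gwas_pos[[ch]] <- data.frame(
      chrom = ch, pos = sort(sample.int(sizes[[ch]], n_bg)),
      stringsAsFactors = FALSE)
  }
  # enrichment applies to every simulated transcription unit: reference
  # genes and candidate models alike
  enrich_spans <- rbind(gene_tbl[, c("chrom", "start", "end")],
                        candidates$transcripts[, c("chrom", "start", "end")])
  extra <- lapply(seq_len(nrow(enrich_spans)), function(i) {
    g <- enrich_spans[i, ]
    len <- g$end - g$start + 1L
    n_x <- rpois(1, len * cfg$gwas_rate * (cfg$gwas_gene_enrich - 1))
    if (n_x == 0L) return(NULL)
    data.frame(chrom = g$chrom,
               pos = g$start + sample.int(len, n_x, replace = TRUE) - 1L,
               stringsAsFactors = FALSE)
  })
  gwas_df <- rbind(do.call(rbind, gwas_pos), do.call(rbind, extra))
  gwas_df <- gwas_df[order(gwas_df$chrom, gwas_df$pos), ]
  gwas <- GenomicRanges::GRanges(gwas_df$chrom,
                                 IRanges::IRanges(gwas_df$pos, gwas_df$pos))

  ## small RNAs: hosted (inside lncRNA introns, same strand), antisense,
  ## and orphan intergenic records
  sr <- list(); sr_truth <- list()
  lnc_intr <- introns_of(reference_a)
  lnc_intr <- lnc_intr[lnc_intr$transcript_id %in% lnc_tbl$tx &
                         lnc_intr$intron_end - lnc_intr$intron_start > 200L, ]
  n_host <- min(10L, nrow(lnc_intr))
  rows <- lnc_intr[sample.int(nrow(lnc_intr), n_host), ]
  for (i in seq_len(n_host)) {
    p <- rows$intron_start[i] + 50L
    sr[[length(sr) + 1L]] <- data.frame(chrom = rows$chrom[i], start = p,
                                        end = p + 21L, strand = rows$strand[i],
                                        label = sprintf("mir%02d", length(sr) + 1L))
    sr_truth[[length(sr_truth) + 1L]] <- "hosted"
  }
  for (i in seq_len(3L)) {
    r2 <- lnc_intr[sample.int(nrow(lnc_intr), 1L), ]
    p <- r2$intron_start + 80L
    sr[[length(sr) + 1L]] <- data.frame(
      chrom = r2$chrom, start = p, end = p + 21L,
      strand = if (r2$strand == "+") "-" else "+",
      label = sprintf("mir%02d", length(sr) + 1L))
    sr_truth[[length(sr_truth) + 1L]] <- "antisense"
  }
  for (i in seq_len(5L)) {
    ch <- sample(chroms, 1L)
    p <- place_intergenic(ch, 22L)
    sr[[length(sr) + 1L]] <- data.frame(chrom = ch, start = p, end = p + 21L,
                                        strand = sample(c("+", "-"), 1L),
                                        label = sprintf("mir%02d", length(sr) + 1L))
    sr_truth[[length(sr_truth) + 1L]] <- "orphan"
  }
  sr_df <- do.call(rbind, sr)
  small_rnas <- GenomicRanges::GRanges(sr_df$chrom,
                                       IRanges::IRanges(sr_df$start, sr_df$end),
                                       strand = sr_df$strand,
                                       label = sr_df$label)
  truth_smallrna <- data.frame(label = sr_df$label,
                               fate = unlist(sr_truth),
                               stringsAsFactors = FALSE)

  ## targeted regions: a detected fraction over candidate exons, the rest
  ## in empty intergenic space
  tgt <- list()
  cand_tx <- candidates$transcripts
  det_idx <- sample.int(nrow(cand_tx), 15L)
  for (i in det_idx)
    tgt[[length(tgt) + 1L]] <- data.frame(
      chrom = cand_tx$chrom[i], start = cand_tx$start[i],
      end = cand_tx$start[i] + 200L, label = "lncRNA_catalog",
      detected = TRUE, stringsAsFactors = FALSE)
  for (i in seq_len(25L)) {
    ch <- sample(chroms, 1L)
    p <- place_intergenic(ch, 400L)
    tgt[[length(tgt) + 1L]] <- data.frame(chrom = ch, start = p,
                                          end = p + 399L, label = "enhancer",
                                          detected = FALSE,
                                          stringsAsFactors = FALSE)
  }
  tgt_df <- do.call(rbind, tgt)
  targets <- GenomicRanges::GRanges(tgt_df$chrom,
                                    IRanges::IRanges(tgt_df$start, tgt_df$end),
                                    label = tgt_df$label)
  truth_targets <- data.frame(idx = seq_len(nrow(tgt_df)),
                              detected = tgt_df$detected)

  ## ---- conservation track ----
  cons <- list()
  for (ch in chroms) {
    n_tiles <- ceiling(sizes[[ch]] / cfg$cons_tile)
    st <- (seq_len(n_tiles) - 1L) * cfg$cons_tile + 1L
    en <- pmin(st + cfg$cons_tile - 1L, sizes[[ch]])
    cons[[ch]] <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, en),
                                         score = rnorm(n_tiles, 0, cfg$cons_sd))
  }
  cons <- unlist(GenomicRanges::GRangesList(cons), use.names = FALSE)
  # planting pool: lncRNA reference transcripts plus intergenic candidates
  # (spatially disjoint sets, so planted labels cannot leak between pool
  # members through shared exons; candidates that copy a reference chain
  # share its bases and are therefore excluded from the truth table)
  cons_pool <- c(lnc_tbl$tx,
                 truth_models$model_id[
                   truth_models$novelty == "novel_gene_intergenic" &
                     truth_models$filter_violation == "none"])
  n_cons <- round(cfg$frac_conserved * length(cons_pool))
  planted_cons <- sample(cons_pool, n_cons)
  both <- rbind(do.call(rbind, ref_rows), do.call(rbind, cand_rows))
  cons_regions <- both[both$transcript_id %in% planted_cons, ]
  pl_intr <- rbind(introns_of(reference_a), introns_of(candidates))
  pl_intr <- pl_intr[pl_intr$transcript_id %in% planted_cons, ]
  elev <- GenomicRanges::reduce(c(
    GenomicRanges::GRanges(cons_regions$chrom,
                           IRanges::IRanges(cons_regions$start, cons_regions$end)),
    GenomicRanges::GRanges(pl_intr$chrom,
                           IRanges::IRanges(pl_intr$intron_start,
                                            pl_intr$intron_start + 1L)),
    GenomicRanges::GRanges(pl_intr$chrom,
                           IRanges::IRanges(pl_intr$intron_end - 1L,
                                            pl_intr$intron_end))))
  hit <- IRanges::overlapsAny(cons, elev, ignore.strand = TRUE)
  S4Vectors::mcols(cons)$score[hit] <-
    rnorm(sum(hit), cfg$cons_conserved_mean, cfg$cons_sd)
  truth_conservation <- data.frame(
    transcript_id = cons_pool,
    label = ifelse(cons_pool %in% planted_cons, "conserved", "background"),
    stringsAsFactors = FALSE)

  ## ---- genome sequences + planted polyA motifs ----
  genome_chr <- lapply(sizes, random_dna)
  all_tx <- rbind(reference_a$transcripts, candidates$transcripts)
  planted_polya <- runif(nrow(all_tx)) < cfg$frac_polya
  scrub <- function(seq_str, lo, hi) {
    # remove any polyA motif starting in [lo, hi] (1-based window on chrom)
    win <- substr(seq_str, lo, hi + 5L)
    for (m in c("AATAAA", "ATTAAA")) {
      repeat {
        p <- regexpr(m, win, fixed = TRUE)[1]
        if (p == -1L) break
        substr(win, p + 2L, p + 2L) <- "C"
      }
    }
    paste0(substr(seq_str, 1L, lo - 1L), win,
           substr(seq_str, hi + 6L, nchar(seq_str)))
  }
  revcomp_chr <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  scrub_minus <- function(seq_str, s3) {
    # scrub on the sense (minus) strand by scrubbing the revcomp window
    lo <- s3; hi <- min(nchar(seq_str), s3 + 55L)
    win_rc <- revcomp_chr(substr(seq_str, lo, hi))
    for (m in c("AATAAA", "ATTAAA")) {
      repeat {
        p <- regexpr(m, win_rc, fixed = TRUE)[1]
        if (p == -1L) break
        substr(win_rc, p + 2L, p + 2L) <- "C"
      }
    }
    paste0(substr(seq_str, 1L, lo - 1L), revcomp_chr(win_rc),
           substr(seq_str, hi + 1L, nchar(seq_str)))
  }
  # two passes: scrub every 3'-end window first, then plant, so no scrub
  # can erase a motif planted for an overlapping neighbour
  for (i in seq_len(nrow(all_tx))) {
    ch <- all_tx$chrom[i]
    if (all_tx$strand[i] == "+")
      genome_chr[[ch]] <- scrub(genome_chr[[ch]],
                                max(1L, all_tx$end[i] - 55L), all_tx$end[i])
    else
      genome_chr[[ch]] <- scrub_minus(genome_chr[[ch]], all_tx$start[i])
  }
  for (i in which(planted_polya)) {
    ch <- all_tx$chrom[i]
    if (all_tx$strand[i] == "+") {
      p <- all_tx$end[i] - 30L  # motif start 30 bp upstream of the 3' end
      substr(genome_chr[[ch]], p, p + 5L) <- "AATAAA"
    } else {
      # sense-strand motif start 30 bp upstream => genomic TTTATT block
      p <- all_tx$start[i] + 30L
      substr(genome_chr[[ch]], p - 5L, p) <- "TTTATT"
    }
  }
  truth_polya <- data.frame(transcript_id = all_tx$transcript_id,
                            planted = planted_polya,
                            stringsAsFactors = FALSE)

  ## ---- genome B, chains, reference B, orthology truth ----
  lnc_ids <- lnc_tbl$gene_id
  n_lost <- round(cfg$frac_ortho_lost * length(lnc_ids))
  n_dup <- round(cfg$frac_ortho_dup * length(lnc_ids))
  fate <- sample(rep(c("lost", "dup", "one"),
                     c(n_lost, n_dup, length(lnc_ids) - n_lost - n_dup)))
  names(fate) <- lnc_ids

  chains_ab <- list()
  genome_b_chr <- list()
  sizes_b <- integer(0)
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    orient <- if (ci %% 2L == 0L) "-" else "+"
    lost <- gene_tbl[gene_tbl$chrom == ch &
                       gene_tbl$gene_id %in% names(fate)[fate == "lost"], ]
    # deletion intervals (0-based half-open), padded, merged
    del <- GenomicRanges::reduce(GenomicRanges::GRanges(
      rep(ch, nrow(lost)),
      IRanges::IRanges(pmax(1L, lost$start - 200L), lost$end + 200L)))
    keep <- GenomicRanges::setdiff(
      GenomicRanges::GRanges(ch, IRanges::IRanges(1L, sizes[[ch]])), del)
    seg_s <- GenomicRanges::start(keep); seg_e <- GenomicRanges::end(keep)
    seg_len <- seg_e - seg_s + 1L
    tgt0 <- cumsum(c(0L, head(seg_len, -1L)))
    bsize <- sum(seg_len)
    blocks <- data.frame(src = seg_s - 1L, tgt = tgt0, size = seg_len)
    chains_ab[[ci]] <- new_chain(
      id = as.character(ci), score = 1000, src_chrom = ch,
      src_size = sizes[[ch]], src_start = blocks$src[1],
      src_end = blocks$src[nrow(blocks)] + blocks$size[nrow(blocks)],
      tgt_chrom = ch, tgt_size = bsize, tgt_strand = orient,
      tgt_start = 0L, tgt_end = bsize, blocks = blocks)
    seq_b <- paste(substring(genome_chr[[ch]], seg_s, seg_e), collapse = "")
    genome_b_chr[[ch]] <- if (orient == "-") revcomp_chr(seq_b) else seq_b
    sizes_b[ch] <- bsize
  }
  chains_ba <- lapply(chains_ab, chain_invert)

  ## reference B: project every non-lost gene's exons through its chain
  b_rows <- list()
  truth_orth <- list()
  for (gi in seq_len(nrow(gene_tbl))) {
    g <- gene_tbl[gi, ]
    f <- if (g$biotype == "lncRNA") fate[[g$gene_id]] else "one"
    if (f == "lost") {
      truth_orth[[g$gene_id]] <- data.frame(gene_a = g$gene_id,
                                            partners = "", class = "none")
      next
    }
    ch_idx <- match(g$chrom, chroms)
    e <- ref_ex[S4Vectors::mcols(ref_ex)$gene_id == g$gene_id]
    pr <- project_interval(chains_ab[[ch_idx]], e)
    fr <- pr$fragments
    mk <- function(suffix) data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(fr)),
      start = GenomicRanges::start(fr), end = GenomicRanges::end(fr),
      strand = as.character(GenomicRanges::strand(fr)),
      transcript_id = paste0(g$gene_id, suffix, ".t1"),
      gene_id = paste0(g$gene_id, suffix), biotype = g$biotype,
      stringsAsFactors = FALSE)
    b_rows[[length(b_rows) + 1L]] <- mk("_b1")
    partners <- paste0(g$gene_id, "_b1")
    cls <- "one_to_one"
    if (f == "dup") {
      b_rows[[length(b_rows) + 1L]] <- mk("_b2")
      partners <- paste(partners, paste0(g$gene_id, "_b2"), sep = ",")
      cls <- "one_to_many"
    }
    if (g$biotype == "lncRNA")
      truth_orth[[g$gene_id]] <- data.frame(gene_a = g$gene_id,
                                            partners = partners, class = cls)
  }
  reference_b <- lnc_annotation(do.call(rbind, b_rows),
                                chrom_sizes = sizes_b)
  truth_orth <- do.call(rbind, truth_orth)
  rownames(truth_orth) <- NULL

  genome_a <- Biostrings::DNAStringSet(unlist(genome_chr))
  genome_b <- Biostrings::DNAStringSet(unlist(genome_b_chr))

  structure(list(
    config = cfg,
    genome_a = genome_a, genome_b = genome_b,
    chrom_sizes_a = sizes, chrom_sizes_b = sizes_b,
    reference_a = reference_a, reference_b = reference_b,
    candidates = candidates,
    candidate_samples = cand_samples, sample_meta = sample_meta,
    junctions = support,
    cage = cage, procap = procap, ccres = ccres, tf_peaks = tf_peaks,
    gwas = gwas, small_rnas = small_rnas, targets = targets,
    conservation = cons,
    chains_ab = chains_ab, chains_ba = chains_ba,
    truth = list(models = truth_models, orthologs = truth_orth,
                 conservation = truth_conservation,
                 polya = truth_polya, small_rnas = truth_smallrna,
                 targets = truth_targets,
                 unique_sample = data.frame(
                   model_id = truth_models$model_id, unique = uniq))),
    class = "sim_bundle")
}

#' Write a synthetic bundle to disk
#'
#' Emits every component in its standard text format (FASTA, GTF, BED,
#' bedGraph, chain, TSVs) plus the truth tables; identical bundles write
#' byte-identical directories.
#'
#' @param bundle A `sim_bundle` from [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(bundle$genome_a, p("genome_a.fa"))
  write_fasta(bundle$genome_b, p("genome_b.fa"))
  write_chrom_sizes(bundle$chrom_sizes_a, p("genome_a.sizes"))
  write_chrom_sizes(bundle$chrom_sizes_b, p("genome_b.sizes"))
  write_gtf(bundle$reference_a, p("reference_a.gtf"))
  write_gtf(bundle$reference_b, p("reference_b.gtf"))
  write_gtf(bundle$candidates, p("candidates.gtf"))
  write_junction_support(bundle$junctions, p("junctions.tsv"))
  write_track(bundle$cage, p("cage.bed"))
  write_track(bundle$procap, p("procap.bed"))
  write_track(bundle$ccres, p("ccres.bed"))
  for (nm in names(bundle$tf_peaks))
    write_track(bundle$tf_peaks[[nm]], p(sprintf("tf_%s.bed", nm)))
  write_track(bundle$gwas, p("gwas.bed"))
  write_track(bundle$small_rnas, p("smallrna.bed"))
  write_track(bundle$targets, p("targets.bed"))
  write_bedgraph(bundle$conservation, p("conservation.bedGraph"))
  write_chain(bundle$chains_ab, p("chains_ab.chain"))
  write_chain(bundle$chains_ba, p("chains_ba.chain"))
  write.table(bundle$candidate_samples, p("candidate_samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$sample_meta, p("sample_meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$truth))
    write.table(bundle$truth[[nm]], p(sprintf("truth_%s.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Precision/recall of stage calls against planted truth
#'
#' @param calls `data.frame` with `id` and `class` columns (a stage's
#'   per-item decisions).
#' @param truth `data.frame` with `id` and `class` columns (planted
#'   labels). Ids must match exactly.
#' @return `data.frame` per class: `class`, `n_truth`, `n_called`, `tp`,
#'   `precision`, `recall`.
#' @export
truth_eval <- function(calls, truth) {
  stopifnot(all(c("id", "class") %in% names(calls)),
            all(c("id", "class") %in% names(truth)))
  if (!setequal(calls$id, truth$id))
    stop("call ids do not match truth ids")
  m <- merge(calls, truth, by = "id", suffixes = c("_call", "_truth"))
  classes <- sort(unique(c(m$class_call, m$class_truth)))
  out <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(m$class_call == cl & m$class_truth == cl)
    n_called <- sum(m$class_call == cl)
    n_truth <- sum(m$class_truth == cl)
    data.frame(class = cl, n_truth = n_truth, n_called = n_called, tp = tp,
               precision = if (n_called) tp / n_called else NaN,
               recall = if (n_truth) tp / n_truth else NaN)
  }))
  rownames(out) <- NULL
  out
}
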