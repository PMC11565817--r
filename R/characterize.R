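# Evaluation of transcript sets against evidence tracks: TSS support (CAGE
# and CAGE-like predictions), polyadenylation motifs, cCRE support and
# TSS-proximity reclassification, transcription-factor coverage profiles,
# GWAS hit densities and meta-profiles, and small-RNA host assignment.

CCRE_CLASSES <- c("PLS", "pELS", "dELS", "CA-H3K4me3", "CA-CTCF", "CA-TF",
                  "CA", "TF")

#' Unique transcription start sites of an annotation
#'
#' The TSS is the strand-aware 5' position of each transcript (start on
#' `+`, end on `-`), deduplicated by exact (chrom, position, strand).
#'
#' @param ann An [lnc_annotation()].
#' @return Width-1 `GRanges` with metadata `transcript_ids` (comma-joined
#'   back-references) and `n_transcripts`.
#' @export
extract_tss <- function(ann) {
  tx <- ann$transcripts
  pos <- ifelse(tx$strand == "+", tx$start, tx$end)
  key <- sprintf("%s:%d:%s", tx$chrom, pos, tx$strand)
  first <- !duplicated(key)
  ids <- tapply(tx$transcript_id, key, paste, collapse = ",")
  n <- table(key)
  GenomicRanges::GRanges(
    tx$chrom[first], IRanges::IRanges(pos[first], pos[first]),
    strand = tx$strand[first],
    transcript_ids = unname(ids[key[first]]),
    n_transcripts = as.integer(n[key[first]]))
}

# positional distance from width-1 points to the nearest interval of a
# track: 0 when covered, else the offset to the nearest interval edge
point_edge_distance <- function(points, track) {
  out <- rep(Inf, length(points))
  if (!length(track)) return(out)
  h <- GenomicRanges::distanceToNearest(points, track, ignore.strand = TRUE)
  gap <- S4Vectors::mcols(h)$distance
  d <- ifelse(gap == 0L &
                IRanges::overlapsAny(points, track,
                                           ignore.strand = TRUE)[S4Vectors::queryHits(h)],
              0L, gap + 1L)
  out[S4Vectors::queryHits(h)] <- d
  out
}

#' TSS support by evidence tracks
#'
#' A TSS is supported by a track iff some track interval lies within
#' `window` bases of it (positional distance 0 when overlapping, else the
#' offset to the nearest interval edge; an edge exactly `window` away still
#' supports).
#'
#' @param tss Width-1 `GRanges` from [extract_tss()].
#' @param evidence Named list of `GRanges` tracks (e.g. CAGE clusters and
#'   TSS predictions).
#' @param window Association window in bp (default 50).
#' @return A list of class `support_summary`: `summary` (per track and
#'   `"any"`: `n_supported`, `n`, `fraction`) and `supported` (logical
#'   matrix, TSS x track).
#' @export
tss_support <- function(tss, evidence, window = 50L) {
  if (is(evidence, "GRanges")) evidence <- list(track = evidence)
  stopifnot(length(evidence) >= 1)
  if (is.null(names(evidence)))
    names(evidence) <- paste0("track", seq_along(evidence))
  supported <- vapply(evidence, function(tr)
    point_edge_distance(tss, tr) <= window, logical(length(tss)))
  supported <- matrix(supported, nrow = length(tss),
                      dimnames = list(NULL, names(evidence)))
  any_sup <- apply(supported, 1L, any)
  summary <- data.frame(
    track = c(names(evidence), "any"),
    n_supported = c(colSums(supported), sum(any_sup)),
    n = length(tss))
  summary$fraction <- summary$n_supported / summary$n
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 supported = cbind(supported, any = any_sup)),
            class = "support_summary")
}

#' Polyadenylation-motif support of transcript 3' ends
#'
#' A transcript is supported iff a canonical polyA motif occurrence on its
#' sense strand starts within `near`..`far` bp upstream of its 3' end.
#'
#' @param ann An [lnc_annotation()].
#' @param genome A named `DNAStringSet` covering the transcripts.
#' @param motifs Motif set searched on the sense strand.
#' @param near,far Window bounds in bp upstream of the 3' end (defaults
#'   10 and 50).
#' @return A list: `fraction`, `supported` (named logical per transcript).
#' @export
polya_support <- function(ann, genome, motifs = c("AATAAA", "ATTAAA"),
                          near = 10L, far = 50L) {
  tx <- ann$transcripts
  if (any(!tx$chrom %in% names(genome)))
    stop("transcript chromosome absent from genome sequence")
  supported <- setNames(logical(nrow(tx)), tx$transcript_id)
  for (i in seq_len(nrow(tx))) {
    csize <- length(genome[[tx$chrom[i]]])
    if (tx$end[i] > csize)
      stop("transcript ", tx$transcript_id[i], " beyond genome sequence")
    if (tx$strand[i] == "+") {
      # upstream offsets far..1 relative to the 3' end (genomic end)
      lo <- tx$end[i] - far; hi <- tx$end[i] - 1L
      if (lo < 1L) lo <- 1L
      if (hi < lo) next
      s <- Biostrings::subseq(genome[[tx$chrom[i]]], lo, hi)
      seq_str <- as.character(s)
      # index j in seq_str = upstream offset (hi - lo + 1) - j + 1... map:
      offset_of <- function(j) tx$end[i] - (lo + j - 1L)
    } else {
      lo <- tx$start[i] + 1L; hi <- tx$start[i] + far
      if (hi > csize) hi <- csize
      if (hi < lo) next
      s <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[tx$chrom[i]]], lo, hi))
      seq_str <- as.character(s)
      # sense position j (1 = offset `hi - start` upstream)
      offset_of <- function(j) hi - tx$start[i] - j + 1L
    }
    for (m in motifs) {
      hits <- gregexpr(m, seq_str, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      offs <- vapply(as.integer(hits), offset_of, integer(1))
      if (any(offs >= near & offs <= far)) {
        supported[i] <- TRUE
        break
      }
    }
  }
  list(fraction = mean(supported), supported = supported)
}

ccre_centers <- function(ccres) {
  # floor((start0 + end0) / 2) in 0-based half-open, expressed 1-based
  c0 <- floor((GenomicRanges::start(ccres) - 1L + GenomicRanges::end(ccres)) / 2)
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(ccres),
                         IRanges::IRanges(c0 + 1L, c0 + 1L))
}

#' cCRE support of TSSs, per regulatory class
#'
#' A TSS is supported by class C iff some class-C cCRE center lies strictly
#' closer than `max_dist` bp (positional distance between the TSS base and
#' the center base).
#'
#' @param tss Width-1 `GRanges`.
#' @param ccres `GRanges` with a `label` column over the cCRE vocabulary
#'   (PLS, pELS, dELS, CA-H3K4me3, CA-CTCF, CA-TF, CA, TF).
#' @param max_dist Strict distance cutoff in bp (default 2000).
#' @return A `support_summary` as in [tss_support()], with one row per
#'   class plus `"any"`.
#' @export
ccre_support <- function(tss, ccres, max_dist = 2000L) {
  lab <- S4Vectors::mcols(ccres)$label
  stopifnot(!is.null(lab))
  bad <- setdiff(unique(lab), CCRE_CLASSES)
  if (length(bad)) stop("unknown cCRE class(es): ", paste(bad, collapse = ", "))
  classes <- intersect(CCRE_CLASSES, unique(lab))
  centers <- ccre_centers(ccres)
  supported <- vapply(classes, function(cl) {
    d <- point_edge_distance(tss, centers[lab == cl])
    d < max_dist
  }, logical(length(tss)))
  supported <- matrix(supported, nrow = length(tss),
                      dimnames = list(NULL, classes))
  any_sup <- apply(supported, 1L, any)
  summary <- data.frame(track = c(classes, "any"),
                        n_supported = c(colSums(supported), sum(any_sup)),
                        n = length(tss))
  summary$fraction <- summary$n_supported / summary$n
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 supported = cbind(supported, any = any_sup)),
            class = "support_summary")
}

#' Reclassify TSS-proximity-dependent cCRE classes
#'
#' Given an enhanced TSS collection: `CA-H3K4me3` records whose center lies
#' strictly within 200 bp of a TSS become `PLS`; `dELS` records whose
#' center lies strictly within 2000 bp become `pELS`. All other records are
#' unchanged and the total record count is conserved. Applying the
#' operation twice with the same TSS set equals applying it once.
#'
#' @param ccres `GRanges` with `label`.
#' @param tss Width-1 `GRanges`.
#' @param promoter_dist,enhancer_dist Strict distance cutoffs (200/2000 bp).
#' @return A list: `ccres` (relabelled copy), `transitions` (`from`, `to`,
#'   `count`, including unchanged classes), `class_fractions` (`class`,
#'   `before`, `after` proportions).
#' @export
reclassify_ccres <- function(ccres, tss, promoter_dist = 200L,
                             enhancer_dist = 2000L) {
  lab <- S4Vectors::mcols(ccres)$label
  d <- point_edge_distance(ccre_centers(ccres), tss)
  new_lab <- lab
  new_lab[lab == "CA-H3K4me3" & d < promoter_dist] <- "PLS"
  new_lab[lab == "dELS" & d < enhancer_dist] <- "pELS"
  out <- ccres
  S4Vectors::mcols(out)$label <- new_lab
  transitions <- as.data.frame(table(from = lab, to = new_lab),
                               stringsAsFactors = FALSE)
  names(transitions)[3] <- "count"
  transitions <- transitions[transitions$count > 0, , drop = FALSE]
  rownames(transitions) <- NULL
  cls <- sort(unique(c(lab, new_lab)))
  class_fractions <- data.frame(
    class = cls,
    before = as.numeric(table(factor(lab, cls)) / length(lab)),
    after = as.numeric(table(factor(new_lab, cls)) / length(new_lab)))
  list(ccres = out, transitions = transitions,
       class_fractions = class_fractions)
}

#' TSS-centered transcription-factor peak coverage profile
#'
#' For each consecutive `window`-bp window from `-flank` to `+flank` around
#' each TSS (strand-oriented: negative offsets are upstream), computes per
#' TF the mean over TSSs of the fraction of window bases covered by that
#' TF's merged peaks, then averages over TFs. Also counts, per TSS, the
#' distinct TFs with at least one peak overlapping the TSS base.
#'
#' @param tss Width-1 `GRanges`.
#' @param peaks_by_tf Named list of `GRanges`, one per TF.
#' @param flank Half-width of the profiled region (default 5000).
#' @param window Window size in bp; must divide `2*flank` (default 500).
#' @return A list: `profile` (`offset_start`, `offset_end`,
#'   `mean_coverage`), `per_tf` (TF x window matrix), `tf_per_tss`
#'   (integer), `mean_tf_per_tss`, `frac_tss_covered`.
#' @export
tf_coverage_profile <- function(tss, peaks_by_tf, flank = 5000L,
                                window = 500L) {
  if ((2L * flank) %% window != 0L)
    stop("window must divide 2*flank")
  if (is(peaks_by_tf, "GRanges")) peaks_by_tf <- list(TF1 = peaks_by_tf)
  stopifnot(length(peaks_by_tf) >= 1)
  n_win <- as.integer(2L * flank / window)
  off_lo <- -flank + (seq_len(n_win) - 1L) * window  # oriented window starts
  pos <- GenomicRanges::start(tss)
  minus <- as.character(GenomicRanges::strand(tss)) == "-"
  n_tss <- length(tss)

  # genomic windows for every (tss, window) pair
  g_start <- integer(n_tss * n_win)
  for (w in seq_len(n_win)) {
    idx <- (w - 1L) * n_tss + seq_len(n_tss)
    g_start[idx] <- ifelse(minus, pos - (off_lo[w] + window) + 1L,
                           pos + off_lo[w])
  }
  chrom <- rep(as.character(GenomeInfoDb::seqnames(tss)), n_win)
  ok <- g_start >= 1L
  wins <- GenomicRanges::GRanges(chrom[ok],
                                 IRanges::IRanges(g_start[ok],
                                                  g_start[ok] + window - 1L))
  win_idx <- rep(seq_len(n_win), each = n_tss)[ok]

  per_tf <- matrix(0, nrow = length(peaks_by_tf), ncol = n_win,
                   dimnames = list(names(peaks_by_tf), NULL))
  tf_at_tss <- matrix(FALSE, nrow = n_tss, ncol = length(peaks_by_tf))
  for (t in seq_along(peaks_by_tf)) {
    merged <- GenomicRanges::reduce(peaks_by_tf[[t]], ignore.strand = TRUE)
    h <- GenomicRanges::findOverlaps(wins, merged, ignore.strand = TRUE)
    if (length(h)) {
      ovw <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(wins)[S4Vectors::queryHits(h)],
        GenomicRanges::ranges(merged)[S4Vectors::subjectHits(h)]))
      cov <- tapply(ovw, win_idx[S4Vectors::queryHits(h)], sum)
      per_tf[t, as.integer(names(cov))] <- as.numeric(cov)
    }
    tf_at_tss[, t] <- IRanges::overlapsAny(tss, merged,
                                                 ignore.strand = TRUE)
  }
  per_tf <- per_tf / (n_tss * window)
  profile <- data.frame(offset_start = off_lo,
                        offset_end = off_lo + window,
                        mean_coverage = colMeans(per_tf))
  list(profile = profile, per_tf = per_tf,
       tf_per_tss = rowSums(tf_at_tss),
       mean_tf_per_tss = mean(rowSums(tf_at_tss)),
       frac_tss_covered = mean(rowSums(tf_at_tss) > 0))
}

# deduplicated base set of a region choice over an annotation
region_bases <- function(ann, region, chrom_sizes = NULL) {
  body <- GenomicRanges::reduce(gene_spans(ann), ignore.strand = TRUE)
  GenomicRanges::strand(body) <- "*"
  if (region == "gene_body") return(body)
  if (region == "exons") {
    ex <- GenomicRanges::reduce(ann$exons, ignore.strand = TRUE)
    GenomicRanges::strand(ex) <- "*"
    return(ex)
  }
  if (region == "complement") {
    if (is.null(chrom_sizes))
      stop("complement region requires chrom_sizes")
    genome <- GenomicRanges::GRanges(names(chrom_sizes),
                                     IRanges::IRanges(1L, as.integer(chrom_sizes)))
    return(GenomicRanges::setdiff(genome, body, ignore.strand = TRUE))
  }
  stop("unknown region: ", region)
}

#' GWAS hit density within a region class
#'
#' Density = hits falling in the deduplicated base set of the region
#' (strand-agnostic), per 100 kb of region length.
#'
#' @param ann An [lnc_annotation()] defining the loci.
#' @param hits `GRanges` of point (1 bp) hit positions; each record counts
#'   once, duplicated positions count once per record.
#' @param region `"gene_body"`, `"exons"` or `"complement"`.
#' @param chrom_sizes Required for `"complement"`.
#' @return A list: `density` (hits per 100 kb), `n_hits`, `region_bp`.
#' @export
gwas_density <- function(ann, hits, region = c("gene_body", "exons",
                                               "complement"),
                         chrom_sizes = NULL) {
  region <- match.arg(region)
  bases <- region_bases(ann, region, chrom_sizes)
  bp <- sum(GenomicRanges::width(bases))
  if (bp == 0L) stop("zero-length region: ", region)
  n <- sum(IRanges::overlapsAny(hits, bases, ignore.strand = TRUE))
  list(density = n / bp * 1e5, n_hits = n, region_bp = bp)
}

#' GWAS density meta-profile along gene bodies and flanks
#'
#' Flanks are binned in absolute bp; gene bodies are rescaled to `n_bins`
#' meta-bins. Bins are strand-oriented (upstream flank first). Densities are
#' hits per 100 kb of aggregated bin length across genes.
#'
#' @param ann An [lnc_annotation()].
#' @param hits Point `GRanges`.
#' @param flank Flank size in bp (default 15000).
#' @param n_bins Number of gene-body meta-bins (default 20).
#' @param flank_bin Flank bin size in bp (default 1000).
#' @return `data.frame`: `bin` (ordered index), `zone`
#'   (upstream/body/downstream), `n_hits`, `bp`, `density`.
#' @export
gwas_profile <- function(ann, hits, flank = 15000L, n_bins = 20L,
                         flank_bin = 1000L) {
  stopifnot(flank %% flank_bin == 0L)
  nf <- as.integer(flank / flank_bin)
  total_bins <- nf + n_bins + nf
  counts <- numeric(total_bins)
  bps <- numeric(total_bins)
  g <- ann$genes
  for (i in seq_len(nrow(g))) {
    s <- g$start[i]; e <- g$end[i]; minus <- g$strand[i] == "-"
    ## oriented bin boundaries as genomic intervals
    up <- lapply(seq_len(nf), function(k) {
      # k-th upstream bin, farthest first (offset -flank + (k-1)*flank_bin)
      if (!minus) c(s - flank + (k - 1L) * flank_bin,
                    s - flank + k * flank_bin - 1L)
      else c(e + flank - k * flank_bin + 1L, e + flank - (k - 1L) * flank_bin)
    })
    bounds <- round(seq(s, e + 1L, length.out = n_bins + 1L))
    body <- lapply(seq_len(n_bins), function(k)
      c(bounds[k], bounds[k + 1L] - 1L))
    if (minus) body <- rev(body)
    down <- lapply(seq_len(nf), function(k) {
      if (!minus) c(e + 1L + (k - 1L) * flank_bin, e + k * flank_bin)
      else c(s - k * flank_bin, s - 1L - (k - 1L) * flank_bin)
    })
    all_bins <- c(up, body, down)
    for (k in seq_len(total_bins)) {
      b <- all_bins[[k]]
      lo <- max(1L, b[1]); hi <- b[2]
      if (hi < lo) next
      bps[k] <- bps[k] + (hi - lo + 1L)
      counts[k] <- counts[k] + sum(GenomicRanges::start(hits) >= lo &
                                     GenomicRanges::start(hits) <= hi &
                                     as.character(GenomeInfoDb::seqnames(hits)) ==
                                     g$chrom[i])
    }
  }
  data.frame(bin = seq_len(total_bins),
             zone = rep(c("upstream", "body", "downstream"),
                        c(nf, n_bins, nf)),
             n_hits = counts, bp = bps,
             density = ifelse(bps > 0, counts / bps * 1e5, 0))
}

#' Host assignment of small RNAs within long transcripts
#'
#' A small RNA is hosted iff its interval lies fully inside some
#' transcript's genomic span (introns included) on the same strand.
#'
#' @param small_rnas Stranded `GRanges` (unstranded records are an error).
#' @param ann An [lnc_annotation()] of candidate host transcripts.
#' @return A list: `table` (per small RNA: `hosted`, comma-joined
#'   `host_transcripts`), `fraction_hosted`.
#' @export
smallrna_hosts <- function(small_rnas, ann) {
  if (any(!as.character(GenomicRanges::strand(small_rnas)) %in% c("+", "-")))
    stop("small RNAs must be stranded")
  spans <- tx_spans(ann)
  h <- GenomicRanges::findOverlaps(small_rnas, spans, type = "within")
  hosted <- logical(length(small_rnas))
  hosts <- character(length(small_rnas))
  if (length(h)) {
    q <- S4Vectors::queryHits(h)
    hosted[unique(q)] <- TRUE
    agg <- tapply(names(spans)[S4Vectors::subjectHits(h)], q,
                  function(x) paste(sort(x), collapse = ","))
    hosts[as.integer(names(agg))] <- unname(agg)
  }
  lab <- S4Vectors::mcols(small_rnas)$label
  tab <- data.frame(
    small_rna = if (!is.null(lab)) lab else as.character(seq_along(small_rnas)),
    hosted = hosted, host_transcripts = hosts, stringsAsFactors = FALSE)
  list(table = tab, fraction_hosted = mean(hosted))
}

#' Side-by-side characterization of several transcript sets
#'
#' Runs TSS, cCRE, polyA, TF and GWAS evaluation for each named set (e.g.
#' novel models, annotated lncRNAs, protein-coding genes, decoys) and
#' tabulates the headline fractions/densities.
#'
#' @param sets Named list of [lnc_annotation()] objects (>= 2).
#' @param evidence A list with any of: `tss_tracks` (named list of
#'   `GRanges`), `ccres`, `tf_peaks` (named list), `gwas`, `genome`
#'   (`DNAStringSet`), `chrom_sizes`.
#' @param tss_window,ccre_dist Windows passed through.
#' @return A `data.frame`, one row per set, columns for each computed
#'   metric (NA when the corresponding evidence was not given).
#' @export
compare_sets <- function(sets, evidence, tss_window = 50L,
                         ccre_dist = 2000L) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  rows <- lapply(names(sets), function(nm) {
    ann <- sets[[nm]]
    tss <- extract_tss(ann)
    row <- data.frame(set = nm, n_transcripts = n_transcripts(ann),
                      n_tss = length(tss))
    row$tss_support_any <- if (!is.null(evidence$tss_tracks))
      tss_support(tss, evidence$tss_tracks, tss_window)$summary$fraction[
        length(evidence$tss_tracks) + 1L] else NA_real_
    row$ccre_support_any <- if (!is.null(evidence$ccres)) {
      s <- ccre_support(tss, evidence$ccres, ccre_dist)$summary
      s$fraction[s$track == "any"]
    } else NA_real_
    row$polya_fraction <- if (!is.null(evidence$genome))
      polya_support(ann, evidence$genome)$fraction else NA_real_
    if (!is.null(evidence$tf_peaks)) {
      tf <- tf_coverage_profile(tss, evidence$tf_peaks)
      row$tf_frac_tss_covered <- tf$frac_tss_covered
      row$tf_mean_per_tss <- tf$mean_tf_per_tss
    } else {
      row$tf_frac_tss_covered <- NA_real_
      row$tf_mean_per_tss <- NA_real_
    }
    row$gwas_body_density <- if (!is.null(evidence$gwas))
      gwas_density(ann, evidence$gwas, "gene_body")$density else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
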