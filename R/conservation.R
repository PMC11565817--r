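# Per-transcript conservation from a per-base score track (phyloP-style
# bedGraph): mean score over exonic bases, mean over splice-site windows,
# and classification against a neutral band, optionally calibrated from
# decoy scores.

#' Neutral band for conservation classification
#'
#' @param lower,upper Band bounds; scores strictly above `upper` classify
#'   `conserved`, strictly below `lower` `accelerated`, the closed interval
#'   in between (boundaries included) `neutral`. Defaults -1.0 / 1.0.
#' @return A list of class `neutral_band`.
#' @export
neutral_band <- function(lower = -1.0, upper = 1.0) {
  if (!(lower < upper)) stop("neutral band requires lower < upper")
  structure(list(lower = lower, upper = upper), class = "neutral_band")
}

#' Mean conservation score over a transcript's exonic bases
#'
#' Arithmetic mean of per-base scores over all exonic positions covered by
#' the track; uncovered bases are excluded from numerator and denominator
#' (gaps are legitimate in score tracks and imputing 0 would bias means
#' toward neutral).
#'
#' @param ann An [lnc_annotation()].
#' @param track `GRanges` with a per-base `score` column (segments of equal
#'   score, bedGraph semantics; segments must not overlap).
#' @return A `data.frame`: `transcript_id`, `exon_mean` (NA when no exonic
#'   base is covered), `n_bases`.
#' @export
transcript_exon_score <- function(ann, track) {
  ids <- ann$transcripts$transcript_id
  agg <- grouped_base_means(ann$exons,
                            S4Vectors::mcols(ann$exons)$transcript_id, track)
  idx <- match(ids, agg$group)
  data.frame(transcript_id = ids,
             exon_mean = agg$mean[idx],
             n_bases = ifelse(is.na(idx), 0L, agg$n[idx]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# one overlap query for all ranges: per-group covered-base count and mean
grouped_base_means <- function(ranges, groups, track) {
  h <- GenomicRanges::findOverlaps(ranges, track, ignore.strand = TRUE)
  if (!length(h))
    return(data.frame(group = character(), mean = numeric(), n = integer()))
  q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(ranges)[q], GenomicRanges::ranges(track)[s]))
  sc <- S4Vectors::mcols(track)$score[s]
  g <- groups[q]
  sums <- tapply(as.numeric(w) * sc, g, sum)
  ns <- tapply(w, g, sum)
  data.frame(group = names(sums), mean = as.numeric(sums) / as.numeric(ns),
             n = as.integer(ns), stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean conservation score over a transcript's splice-site windows
#'
#' Pools, across all junctions of a spliced transcript, the first
#' `site_window` intronic bases at each donor and the last `site_window` at
#' each acceptor (default 2 bp: the invariant GT/AG dinucleotides), then
#' averages per-base scores over covered positions. Monoexonic transcripts
#' get NA. The result depends only on the intron chain, never the termini.
#'
#' @inheritParams transcript_exon_score
#' @param site_window Bases taken at each intron end (default 2).
#' @return A `data.frame`: `transcript_id`, `junction_mean`, `n_bases`.
#' @export
transcript_junction_score <- function(ann, track, site_window = 2L) {
  ids <- ann$transcripts$transcript_id
  intr <- introns_of(ann)
  out <- data.frame(transcript_id = ids, junction_mean = NA_real_,
                    n_bases = 0L, stringsAsFactors = FALSE)
  if (!nrow(intr)) return(out)
  w <- pmin(site_window, intr$intron_end - intr$intron_start + 1L)
  sites <- GenomicRanges::GRanges(
    rep(intr$chrom, 2L),
    IRanges::IRanges(c(intr$intron_start, intr$intron_end - w + 1L),
                     c(intr$intron_start + w - 1L, intr$intron_end)),
    tx = rep(intr$transcript_id, 2L))
  # short introns: merge the two site windows so bases count once
  sites <- unlist(GenomicRanges::reduce(
    GenomicRanges::split(sites, S4Vectors::mcols(sites)$tx)))
  agg <- grouped_base_means(sites, names(sites), track)
  idx <- match(ids, agg$group)
  hit <- !is.na(idx)
  out$junction_mean[hit] <- agg$mean[idx[hit]]
  out$n_bases[hit] <- agg$n[idx[hit]]
  out
}

#' Classify scores against a neutral band
#'
#' @param score Numeric vector (NA allowed).
#' @param band A [neutral_band()].
#' @return Character vector in `conserved`/`neutral`/`accelerated`
#'   (`unclassified` for NA scores).
#' @export
classify_conservation <- function(score, band = neutral_band()) {
  stopifnot(is(band, "neutral_band"))
  out <- rep("unclassified", length(score))
  out[!is.na(score) & score > band$upper] <- "conserved"
  out[!is.na(score) & score < band$lower] <- "accelerated"
  out[!is.na(score) & score >= band$lower & score <= band$upper] <- "neutral"
  out
}

#' Calibrate a neutral band from decoy scores
#'
#' The band is the empirical central-quantile interval of decoy exon means:
#' decoys sit in unannotated space, so their score distribution estimates
#' the neutral background.
#'
#' @param decoy_scores Numeric vector of decoy exon means (>= 100 values).
#' @param central_mass Central probability mass the band must contain.
#' @return A [neutral_band()].
#' @export
calibrate_band <- function(decoy_scores, central_mass = 0.95) {
  decoy_scores <- decoy_scores[!is.na(decoy_scores)]
  if (length(decoy_scores) < 100L)
    stop("need >= 100 decoy scores to calibrate a band")
  a <- (1 - central_mass) / 2
  q <- quantile(decoy_scores, c(a, 1 - a), names = FALSE)
  if (!(q[1] < q[2]))
    stop("degenerate decoy score distribution: band would be empty")
  neutral_band(q[1], q[2])
}

#' Conservation summary across transcript sets
#'
#' @param sets Named list of [lnc_annotation()] objects.
#' @param track Per-base score track (`GRanges` with `score`).
#' @param band A [neutral_band()].
#' @param site_window Splice-site window (see
#'   [transcript_junction_score()]).
#' @param breaks Histogram breaks for the score frequency tables.
#' @return A list: `fractions` (per set and score kind: fraction
#'   conserved/neutral/accelerated/unclassified), `histograms` (per set:
#'   `mid`, `exon_count`, `junction_count`), `scores` (per-set score
#'   tables).
#' @export
conservation_summary <- function(sets, track, band = neutral_band(),
                                 site_window = 2L,
                                 breaks = seq(-10, 10, by = 0.25)) {
  stopifnot(!is.null(names(sets)))
  fractions <- list(); histograms <- list(); scores <- list()
  for (nm in names(sets)) {
    es <- transcript_exon_score(sets[[nm]], track)
    js <- transcript_junction_score(sets[[nm]], track, site_window)
    cls_e <- classify_conservation(es$exon_mean, band)
    cls_j <- classify_conservation(js$junction_mean, band)
    frac <- function(cls) {
      n <- length(cls)
      data.frame(conserved = sum(cls == "conserved") / n,
                 neutral = sum(cls == "neutral") / n,
                 accelerated = sum(cls == "accelerated") / n,
                 unclassified = sum(cls == "unclassified") / n)
    }
    fractions[[length(fractions) + 1L]] <- cbind(
      data.frame(set = nm, kind = c("exon", "junction")),
      rbind(frac(cls_e), frac(cls_j)))
    clamp <- function(x) pmin(pmax(x, min(breaks)), max(breaks))
    he <- graphics::hist(clamp(es$exon_mean[!is.na(es$exon_mean)]), breaks = breaks,
               plot = FALSE)
    hj <- graphics::hist(clamp(js$junction_mean[!is.na(js$junction_mean)]),
               breaks = breaks, plot = FALSE)
    histograms[[nm]] <- data.frame(mid = he$mids, exon_count = he$counts,
                                   junction_count = hj$counts)
    scores[[nm]] <- merge(es, js, by = "transcript_id",
                          suffixes = c("_exon", "_junction"))
  }
  list(fractions = do.call(rbind, fractions), histograms = histograms,
       scores = scores)
}
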