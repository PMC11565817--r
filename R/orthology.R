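# Cross-species orthology from correct-strand exon synteny: gene exon
# unions are projected through chain alignments, candidate partners must
# receive at least a minimum fraction of the projected bases on the correct
# strand, and calls are made under a strict reciprocal definition on the
# bipartite candidate graph.

#' Parameters for exon-synteny orthology
#'
#' @param min_exon_overlap_fraction Minimum fraction of projected bases that
#'   must land on a candidate target gene's exons (default 0.5).
#' @param min_exons_mapped Minimum fraction of a gene's exons that must map
#'   (>= 1 bp each) for the gene to have candidates at all (default 0.5).
#' @return A list of class `orthology_params`. The strand rule is fixed:
#'   overlap counts only on the strand implied by the chain orientation
#'   (source strand, flipped for minus-orientation chains).
#' @export
orthology_params <- function(min_exon_overlap_fraction = 0.5,
                             min_exons_mapped = 0.5) {
  stopifnot(min_exon_overlap_fraction > 0, min_exon_overlap_fraction <= 1,
            min_exons_mapped > 0, min_exons_mapped <= 1)
  structure(list(min_exon_overlap_fraction = min_exon_overlap_fraction,
                 min_exons_mapped = min_exons_mapped),
            class = "orthology_params")
}

# merged (union) exon set of one gene, as GRanges on the gene's strand
gene_exon_union <- function(ann, gene_id) {
  ex <- ann$exons[S4Vectors::mcols(ann$exons)$gene_id == gene_id]
  GenomicRanges::reduce(ex)
}

#' Project a gene's exons to the other genome
#'
#' The gene's union-of-transcript exon set is projected exon by exon; when
#' several chains cover an exon the highest-scoring one wins (liftover
#' best-chain convention).
#'
#' @param ann Source [lnc_annotation()].
#' @param gene_id Gene to project.
#' @param chains List of `chain_alignment` objects (source = `ann` genome).
#' @return A list: `fragments` (projected `GRanges` on the target genome,
#'   strand already chain-adjusted), `per_exon_fraction` (mapped bp fraction
#'   per exon), `frac_exons_mapped` (fraction of exons with >= 1 mapped bp),
#'   `projected_bp` (total mapped bases).
#' @export
project_gene <- function(ann, gene_id, chains) {
  exons <- gene_exon_union(ann, gene_id)
  n <- length(exons)
  per_exon <- numeric(n)
  frags <- list()
  chrom <- as.character(GenomeInfoDb::seqnames(exons))
  for (k in seq_len(n)) {
    covering <- Filter(function(ch)
      ch$src_chrom == chrom[k] &&
        ch$src_start < GenomicRanges::end(exons)[k] &&
        ch$src_end > GenomicRanges::start(exons)[k] - 1L, chains)
    if (!length(covering)) next
    best <- covering[[which.max(vapply(covering, `[[`, numeric(1), "score"))]]
    pr <- project_interval(best, exons[k])
    per_exon[k] <- pr$mapped_fraction
    if (length(pr$fragments)) frags[[length(frags) + 1L]] <- pr$fragments
  }
  fragments <- if (length(frags))
    GenomicRanges::sort(do.call(c, unname(frags)), ignore.strand = TRUE)
  else GenomicRanges::GRanges()
  list(fragments = fragments,
       per_exon_fraction = per_exon,
       frac_exons_mapped = if (n) mean(per_exon > 0) else 0,
       projected_bp = sum(GenomicRanges::width(fragments)))
}

#' Candidate orthologs of one gene
#'
#' Target genes whose exons overlap the projected exon set on the correct
#' strand, with overlap fraction = overlapped projected bp / total projected
#' bp; kept iff the fraction reaches `params$min_exon_overlap_fraction` and
#' the gene itself had at least `params$min_exons_mapped` of its exons
#' mapped.
#'
#' @param ann Source annotation; `gene_id` a gene therein.
#' @param target Target [lnc_annotation()].
#' @param chains Chains from the source to the target genome.
#' @param params An [orthology_params()].
#' @return `data.frame` with `target_gene` and `fraction`, best first.
#' @export
candidate_orthologs <- function(ann, gene_id, target, chains,
                                params = orthology_params()) {
  empty <- data.frame(target_gene = character(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  proj <- project_gene(ann, gene_id, chains)
  if (proj$frac_exons_mapped < params$min_exons_mapped ||
      proj$projected_bp == 0) return(empty)
  tex <- target$exons
  h <- GenomicRanges::findOverlaps(proj$fragments, tex) # strand-matched
  if (!length(h)) return(empty)
  q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
  genes <- S4Vectors::mcols(tex)$gene_id[s]
  out <- lapply(unique(genes), function(g) {
    gex <- GenomicRanges::reduce(tex[S4Vectors::mcols(tex)$gene_id == g])
    ov <- GenomicRanges::intersect(GenomicRanges::reduce(proj$fragments), gex)
    data.frame(target_gene = g,
               fraction = sum(GenomicRanges::width(ov)) / proj$projected_bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$fraction >= params$min_exon_overlap_fraction, , drop = FALSE]
  out[order(-out$fraction, out$target_gene), , drop = FALSE]
}

#' Strict reciprocal orthology between two annotations
#'
#' An edge a-b exists iff b is a candidate of a through the A-to-B chains
#' AND a is a candidate of b through the B-to-A chains. Connected components
#' of the bipartite edge graph are labelled `one_to_one`, `one_to_many`,
#' `many_to_one` or `many_to_many` by the number of A and B genes they
#' contain; genes with no edge are `none`.
#'
#' @param annot_a,annot_b [lnc_annotation()] objects (restrict to the
#'   biotype of interest before calling, e.g. lncRNA genes).
#' @param chains_ab,chains_ba Chain lists for the two directions.
#' @param params An [orthology_params()].
#' @return A list of class `orthology_result`: `calls` (per gene: `gene`,
#'   `genome` `"A"`/`"B"`, `class`, comma-joined `partners`) and `edges`
#'   (`gene_a`, `gene_b`, `fraction_ab`, `fraction_ba`, `class`).
#' @export
reciprocal_orthology <- function(annot_a, annot_b, chains_ab, chains_ba,
                                 params = orthology_params()) {
  ga <- annot_a$genes$gene_id
  gb <- annot_b$genes$gene_id
  cand_ab <- setNames(lapply(ga, function(g)
    candidate_orthologs(annot_a, g, annot_b, chains_ab, params)), ga)
  cand_ba <- setNames(lapply(gb, function(g)
    candidate_orthologs(annot_b, g, annot_a, chains_ba, params)), gb)

  edges <- list()
  for (a in ga) {
    for (i in seq_len(nrow(cand_ab[[a]]))) {
      b <- cand_ab[[a]]$target_gene[i]
      back <- cand_ba[[b]]
      if (a %in% back$target_gene)
        edges[[length(edges) + 1L]] <- data.frame(
          gene_a = a, gene_b = b,
          fraction_ab = cand_ab[[a]]$fraction[i],
          fraction_ba = back$fraction[back$target_gene == a],
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(gene_a = character(), gene_b = character(),
               fraction_ab = numeric(), fraction_ba = numeric(),
               stringsAsFactors = FALSE)

  calls <- data.frame(gene = c(ga, gb),
                      genome = rep(c("A", "B"), c(length(ga), length(gb))),
                      class = "none", partners = "",
                      stringsAsFactors = FALSE)
  edges$class <- character(nrow(edges))
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("A:", edges$gene_a),
                 to = paste0("B:", edges$gene_b)), directed = FALSE)
    comp <- igraph::components(g)$membership
    for (ci in unique(comp)) {
      vs <- names(comp)[comp == ci]
      na <- sum(startsWith(vs, "A:")); nb <- sum(startsWith(vs, "B:"))
      cls <- if (na == 1 && nb == 1) "one_to_one"
        else if (na == 1) "one_to_many"
        else if (nb == 1) "many_to_one"
        else "many_to_many"
      a_ids <- sub("^A:", "", vs[startsWith(vs, "A:")])
      b_ids <- sub("^B:", "", vs[startsWith(vs, "B:")])
      edges$class[edges$gene_a %in% a_ids] <- cls
      ia <- calls$genome == "A" & calls$gene %in% a_ids
      ib <- calls$genome == "B" & calls$gene %in% b_ids
      calls$class[ia] <- cls
      calls$class[ib] <- cls
      for (i in which(ia))
        calls$partners[i] <- paste(sort(edges$gene_b[edges$gene_a == calls$gene[i]]),
                                   collapse = ",")
      for (i in which(ib))
        calls$partners[i] <- paste(sort(edges$gene_a[edges$gene_b == calls$gene[i]]),
                                   collapse = ",")
    }
  }
  structure(list(calls = calls, edges = edges), class = "orthology_result")
}

#' Orthology status of a disease-associated gene list
#'
#' @param result An `orthology_result` from [reciprocal_orthology()].
#' @param disease_genes `data.frame` with a `gene_id` column (genome A ids);
#'   other columns (e.g. `source`) are carried through.
#' @return A list: `table` (per listed gene: orthology class and partners;
#'   genes absent from the annotation are reported with class
#'   `not_in_annotation`), `n_listed`, `n_with_ortholog`,
#'   `fraction_with_ortholog`.
#' @export
disease_ortholog_lookup <- function(result, disease_genes) {
  stopifnot(is.data.frame(disease_genes))
  if (nrow(disease_genes) == 0L)
    return(list(table = data.frame(gene_id = character(), class = character(),
                                   partners = character()),
                n_listed = 0L, n_with_ortholog = 0L,
                fraction_with_ortholog = NaN))
  ca <- result$calls[result$calls$genome == "A", ]
  idx <- match(disease_genes$gene_id, ca$gene)
  tab <- disease_genes
  tab$class <- ifelse(is.na(idx), "not_in_annotation", ca$class[idx])
  tab$partners <- ifelse(is.na(idx), "", ca$partners[idx])
  has <- tab$class %in% c("one_to_one", "one_to_many", "many_to_one",
                          "many_to_many")
  list(table = tab, n_listed = nrow(tab), n_with_ortholog = sum(has),
       fraction_with_ortholog = mean(has))
}
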