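---
title: "lncforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind each pipeline
stage, the parameters that matter, the generative model of the synthetic
bundle, and the numerical conventions. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinates and containers

All internal containers are GenomicRanges/IRanges objects, so internal
coordinates are **1-based closed** — the native convention of the
R/Bioconductor stack this package is written in. Conversion happens only
at format boundaries: GTF (1-based inclusive) and BED/bedGraph (0-based
half-open) are handled by `rtracklayer`; the UCSC chain format keeps its
native 0-based block offsets inside the `chain_alignment` object and is
converted inside `project_interval()`; the 5-column junction TSV stores
0-based half-open donor/acceptor offsets on disk and 1-based closed
intron coordinates in memory. A single internal convention eliminates a
whole class of off-by-one errors; every boundary conversion is covered by
a round-trip test.

Transcripts are always stranded (`+`/`-`); the unstranded `.`/`*` state is
permitted only on evidence tracks, because every transcript-level analysis
(TSS, polyA, hosting, antisense rules) is strand-aware.

## Intron-chain identity and merging

A spliced transcript is identified by `(chrom, strand, ordered
donor–acceptor list)`; transcript termini are deliberately ignored, since
long-read models of one transcript routinely differ at their ends. The
merged representative takes the 5′-most start and 3′-most end over its
members, preserving the full evidence span; member ids are kept as
provenance so original termini remain recoverable.

Monoexonic models have an empty chain, so chain identity cannot separate
them. They merge when on the same strand with **≥ 50% reciprocal span
overlap**, the standard single-linkage fallback for unspliced models;
grouping is the transitive closure of that pairwise relation (union-find).
The same rule decides whether a monoexonic candidate is "known" relative
to a monoexonic reference transcript in `classify_novelty()` — chain
identity is undefined there, and reciprocal overlap is the least
surprising substitute.

Novelty categories are assigned with a fixed precedence — known >
same-strand exonic overlap > intronic containment > antisense exonic
overlap > intergenic — which makes the call deterministic when a model
satisfies several descriptions at once (e.g. a model overlapping one gene
exonically and sitting inside another's intron).

## Acceptance filtering

Three rejection predicates, each independent of the others, so the
accepted set does not depend on application order (asserted by test):

- **antisense_pc** — ≥ 1 bp exon–exon overlap with a protein-coding gene
  on the opposite strand. Exon-level (not span-level) overlap is used so
  that models lying wholly within protein-coding *introns* are retained;
  span-level overlap would discard them although they are analyzable.
- **pseudogene_contained** — the model's span lies entirely within a
  pseudogene locus span, on either strand. Containment is strand-agnostic
  because annotated pseudogene orientation is unreliable and the rule is
  about genomic bounds, not sense.
- **low_junction_support** — any intron with short-read support strictly
  below `min_junction_reads` (default **50** reads; a count of exactly 50
  passes). Monoexonic models pass vacuously. The threshold is exposed in
  `filter_config()`.

Models whose exons bridge two or more distinct same-strand lncRNA genes
are *flagged*, never auto-rejected: silently fusing annotated loci is the
one mistake an annotation pipeline must not make, so these cases are left
to curation. Reasons accumulate per model; a model is accepted iff it has
none.

## Decoy models

Each decoy copies the exon/intron length sequence and the strand of a
uniformly sampled source transcript and is placed uniformly on the same
chromosome, rejecting any placement whose span intersects an annotated
locus span extended by `buffer` (default **1000 bp**) or runs off the
chromosome (`max_attempts` per decoy, default 1000, then a hard error
naming the structure). This construction preserves the two properties the
downstream comparisons rely on — the transcript-structure statistics of
the real annotation, and guaranteed non-genic placement — while leaving
sequence composition untouched. Matching GC or repeat context is out of
scope. Placement uses only integer RNG draws under `set.seed(seed)`, so a
seed fully determines the output across platforms.

## Chain projection and orthology

`project_interval()` implements liftover semantics: intersect the query
with each ungapped block, carry offsets to the target, drop gap bases.
For minus-orientation chains the block offsets live on the reversed
target sequence (chain-file convention); fragments are converted to
forward-strand coordinates and their strand is flipped relative to the
query. `chain_invert()` produces the opposite-direction chain (an
involution, tested as such), so one chain file suffices for both
directions when needed.

Gene-level orthology projects the **union of transcript exons** per gene
(the published counts this mirrors are gene-level). When several chains
cover an exon, the highest-scoring chain wins — the liftover best-chain
convention, and deterministic. A target gene is a candidate iff the
projected bases overlapping its exons **on the strand implied by the
chain orientation** reach `min_exon_overlap_fraction` (default 0.5) of
all projected bases, and the source gene had at least `min_exons_mapped`
(default 0.5) of its exons mapped at ≥ 1 bp. These two defaults are this
package's own choices, exposed as parameters: the upstream tool this
stage emulates does not publish its exact thresholds, so they are
documented stand-ins, not reproduced constants. An orthology edge
requires candidacy in both directions (strict reciprocity); connected
components of the bipartite edge graph are labelled one-to-one /
one-to-many / many-to-one / many-to-many, and edge-less genes are `none`.

## Evidence evaluation

Distance conventions follow each evidence type's own definition:

- **TSS–cluster distance** (CAGE and CAGE-like prediction tracks) is the
  positional offset to the nearest cluster *edge*, 0 when covered; a TSS
  is supported within ± `window` = **50 bp** (an edge exactly 50 bp away
  supports; 51 does not). Prediction tracks are consumed under the same
  contract as CAGE — one uniform evidence interface.
- **polyA support**: a canonical motif (AATAAA or ATTAAA) on the
  transcript's sense strand must *start* within **10–50 bp** upstream of
  the 3′ end (5 bp: too close; 55 bp: too far).
- **TSS–cCRE distance** uses the element *center*, `floor((start0 +
  end0)/2)`, with a strict `< 2000 bp` cutoff (1999 supports, 2000 does
  not). Reclassification applies exactly two transitions against an
  enhanced TSS set — CA-H3K4me3→PLS at `< 200 bp`, dELS→pELS at
  `< 2000 bp` — conserves the record count, and is idempotent.
- **TF profiles**: per TF, peaks are merged and the covered fraction of
  each consecutive **500 bp** window from −5000 to +5000 around each TSS
  is averaged over TSSs, then over TFs. Windows are strand-oriented
  (negative = upstream), so minus-strand profiles flip before
  aggregation. The window must divide 2×flank exactly.
- **GWAS hits** are strand-agnostic points; each record counts once.
  Densities are hits per **100 kb** of the deduplicated base set of the
  region (gene bodies, exons, or the genomic complement). The meta-profile
  bins flanks in absolute bp (default 1 kb bins over ±15 kb) and rescales
  gene bodies to `n_bins` meta-bins, strand-oriented.
- **Small-RNA hosting** requires full containment in a transcript's
  genomic span — introns included, since intron-processed precursors are
  the canonical case — on the same strand.

## Conservation

Per-transcript scores are arithmetic means of per-base track scores over
(i) exonic positions and (ii) splice-site windows: the first
`site_window` intronic bases at each donor plus the last `site_window` at
each acceptor, pooled across junctions. `site_window` defaults to **2 bp**
— the invariant GT/AG dinucleotides — and is a parameter because the
appropriate window is a judgment call; the junction mean depends only on
the intron chain, never the termini (tested). Track-uncovered bases are
excluded from numerator and denominator rather than imputed as 0: score
tracks legitimately have gaps, and zero-imputation would drag means
toward neutral.

Classification uses a neutral band, default **(−1.0, +1.0)** with
boundary values classified neutral (the band is read as a closed
interval; any convention would do, this one is documented and tested).
`calibrate_band()` derives an empirical band as the central
`central_mass` (default 95%) quantile interval of decoy exon means —
decoys sit in unannotated space, so their score distribution estimates
the neutral background.

## The synthetic bundle

`simulate_bundle()` emulates the statistical structure the analyses
assume, at desk scale (defaults: two chromosomes, 0.7 Mb total, 58
reference genes, 60 candidate models — sizes chosen so the full pipeline
and its tests run comfortably on one CPU):

- **Genomes**: uniform-random nucleotides; no repeat structure or GC
  heterogeneity (no in-scope analysis depends on them). PolyA motifs are
  planted 30 bp upstream of a labelled fraction of 3′ ends and scrubbed
  from all other 3′-end windows (scrub first, then plant, so overlapping
  termini cannot erase a planted motif).
- **Genes**: log-normal exon/intron lengths (location log 150 / log 700,
  spread 0.4 / 0.5), 1 + Poisson exon counts — round numbers in the range
  annotated lncRNA structures occupy.
- **Candidates**: planted classes at configured fractions — chain copies
  of reference transcripts (known), exon-skips (novel), intergenic
  placements, antisense-to-protein-coding constructions,
  pseudogene-contained models, and weak-junction models. Sources are
  drawn without replacement where the pool allows, so candidate chains
  are unique and merging is exactly invertible against truth.
- **Junction counts**: negative binomial (mean 300, dispersion 2) shifted
  to ≥ 50 for supported junctions; planted weak introns draw uniformly
  from 1–49. The analyses depend only on the threshold crossing, not the
  count law, so the family is a configuration choice.
- **Evidence tracks**: CAGE-like clusters at TSSs with Gaussian jitter
  (sd 10 bp) plus uniform background; cCREs placed with class-consistent
  TSS proximity plus deliberately misclassified records (CA-H3K4me3 and
  dELS near TSSs) for the reclassification stage; background distal
  elements are rejection-sampled to stay ≥ 2.2 kb from every TSS so their
  class remains stable under reclassification; TF peaks at uniform
  background density plus TSS-centered peaks; GWAS hits Poisson at
  1×10⁻⁴/bp with a 2× multiplier over every simulated transcription unit.
- **Conservation**: 10 bp tiles, N(0, 0.3) background, planted conserved
  transcripts at N(3.0, 0.3) over exons and splice sites. The planting
  pool is restricted to spatially disjoint transcripts (reference lncRNAs
  and intergenic candidates) so truth labels cannot leak through shared
  exons.
- **Genome B and chains**: genome B is genome A with planted gene
  deletions (chain gaps) and 1:2 duplications; every second chromosome is
  reverse-complemented and carried by a minus-orientation chain, so the
  reversed-coordinate code path is always exercised. The B annotation is
  produced by projecting A genes through the chains themselves, which
  makes chain/annotation consistency exact by construction. Duplicated
  partners share the projected locus, the configuration under which a
  strict reciprocal definition genuinely yields 1:2 calls at the default
  overlap threshold.

What the generator does **not** emulate — and hence what green tests do
not show about real data: read-level noise and truncation artifacts,
repeat-driven mismapping, GC/composition biases, expression-level
variation beyond junction counts, many-to-many orthology tangles from
large duplication families, and the long-tail size distribution of real
chromosomes. The tests establish that the *operations* are correct under
their stated contracts, not that the biological conclusions transfer.

## Problem sizes

The default test run simulates one bundle (60 candidates, 58 reference
genes) shared across test files, plus dedicated instances where a
property needs scale: 500 random models against the pairwise merging
oracle, 1000 decoys for the placement guarantees, exhaustive per-base
projection over every chain base (chains ≤ 10 kb span), 10,000 random
cCREs for the reclassification algebra, and 2000 uniform peaks over a
2 Mb toy chromosome for profile flatness. `scripts/acceptance.R` runs the
full pipeline once with 500 decoys.

## Known limitations

- Monoexonic "known" calls use reciprocal overlap, not chain identity;
  borderline 50% overlaps flip categories discontinuously.
- Orthology thresholds (0.5/0.5) are stand-ins, not published values;
  sensitivity to them is not explored here.
- `tf_coverage_profile` clamps windows at chromosome starts; bases beyond
  the chromosome count as uncovered rather than shrinking the window.
- The GWAS meta-profile rescales gene bodies shorter than `n_bins` bp
  into degenerate bins (empty bins get density 0).
- Hypothesis testing of enrichments (e.g. real vs decoy significance) is
  deliberately left to downstream use; the package reports the
  quantities, not p-values.
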