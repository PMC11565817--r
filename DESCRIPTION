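Package: lncforge
Title: Integration and Characterization of Capture Long-Read lncRNA Transcript Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for integrating capture long-read sequencing (CLS)
    transcript models into a reference lncRNA annotation and characterizing the
    result. Implements intron-chain collapsing and novelty classification against
    a reference, TAGENE-style acceptance filtering (antisense-to-protein-coding,
    pseudogene containment, short-read splice-junction support), construction of
    intergenic decoy transcript models as a genomic background baseline,
    chain-based exon-synteny reciprocal orthology between two genomes, evaluation
    of transcript sets against TSS/cCRE/transcription-factor/GWAS/small-RNA
    evidence tracks, and per-transcript conservation scoring against a neutral
    band. A seeded synthetic-data generator produces every input the pipeline
    consumes, with planted ground truth, so each stage is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
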