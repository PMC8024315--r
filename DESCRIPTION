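Package: cregnet
Title: Consensus Gene Regulatory Networks from Paired Expression and
    Chromatin Accessibility Replicates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds context-specific gene regulatory networks from paired
    gene expression and chromatin accessibility data, one network per
    biological replicate, and integrates the replicate networks into a
    single consensus network by a projected fixed-point optimization that
    trades replicate fidelity, strength/cis-regulatory-module consistency,
    base continuity and sparsity. Each edge is a transcription factor to
    target gene regulation mediated by a cis-regulatory module (CRM), a set
    of accessible regulatory elements carrying the factor's binding motif.
    Downstream tools score networks against gold standards, reveal network
    architecture (TF modules, dense TF subnetwork by quadratic programming,
    upstream/core/downstream roles), and annotate genetic variants and
    evolutionary elements against the network (subnetwork extraction, SNP
    enrichment curves, allele-specific motif rescoring, shuffle-based
    empirical overlap p-values). A seeded synthetic-data generator provides
    toy genomes, motifs, ground-truth networks and SNP panels for testing
    and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pheatmap,
    knitr,
    rmarkdown
biocViews: NetworkInference, GeneRegulation, Transcription, ATACSeq,
    GeneExpression, MotifAnnotation, GenomeWideAssociation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
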