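Package: epidyn
Title: Multi-Omic Chromatin Dynamics Across Brain Development and Aging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates per-stage histone-mark, DNase hypersensitivity, Pol2
    and CTCF signals with Hi-C contact maps, promoter DNA methylation and
    expression across an ordered developmental time course. Computes gene
    active signals (GAS), calls stage-specific genes, tracks bivalent promoter
    state transitions and the H3K27me3-to-5mC handoff, derives A/B compartments,
    insulation-score TADs and a TAD-change taxonomy, calls enhancer-promoter
    loops, classifies super versus typical enhancers, and provides exact
    enrichment statistics. A synthetic-data generator with planted ground truth
    makes every caller testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    limma,
    fgsea,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, HiC, FunctionalGenomics, GeneRegulation, Software
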