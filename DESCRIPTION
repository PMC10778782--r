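Package: eqtlNet
Title: Expression QTL Mapping, Hotspot Detection and Regulatory Network
    Extraction for F1 Mapping Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide expression quantitative trait locus (eQTL)
    analysis in outbred F1 mapping populations, motivated by wood-formation
    gene regulation in shrub willow. Reads genotypes (VCF), gene models (GFF3)
    and FPKM expression tables; filters and rank-normalizes expression;
    filters SNPs by quality, minor allele frequency and missingness and
    classifies their functional context; tests every SNP-gene pair with an
    additive linear model; chains significant SNPs into eQTL blocks and
    classifies them cis or trans; detects trans-eQTL hotspots by sliding-window
    counting against a permutation-derived threshold; and screens candidate
    regulator-target pairs by co-expression and differential-expression rules
    into regulatory networks. A synthetic-data generator plants known cis and
    trans effects, hotspots and regulatory motifs so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    vcfR,
    rtracklayer,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
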