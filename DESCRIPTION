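Package: cnvpop
Title: Copy-Number-Variation Population Genomics from Binned Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible pipeline for population-level analysis of copy
    number variation (CNV) from binned whole-genome read-depth tracks:
    GC-bias correction, exact penalized least-squares changepoint
    segmentation, diploid copy-state calling with significance and
    mapping-quality filters, merging of per-sample calls into CNV regions
    (CNVRs) with a carrier-frequency filter, gene-model annotation of CNVRs
    (including the frameshift-deletion rule for coding deletions),
    CNVR-based population structure (neighbor-joining trees, variance
    standardized PCA, admixture-model EM), Weir-Cockerham F_ST selection
    scans with top-percentile thresholding, and local hypergeometric
    gene-set enrichment. A synthetic-cohort generator with saved truth
    (Balding-Nichols differentiated allele frequencies, Dirichlet
    admixture, Poisson depth with GC bias and mapping-quality-zero
    fractions) makes every stage verifiable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
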