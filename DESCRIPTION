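Package: chromoplast
Title: Chromatin Packing, Transcriptional Plasticity and Heterogeneity Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking nanoscale chromatin packing to
    transcriptional plasticity in cancer-stem-cell biology. Converts partial
    wave spectroscopic (PWS) image cubes into per-pixel chromatin packing
    scaling maps and nuclear averages (D_n) with population comparison;
    quantifies intracellular transcriptional plasticity from bulk RNA-seq via
    TPM normalization, fold-change gating, baseline-quantile response curves
    and lowest-decile fold-change density summaries; computes the
    radius-of-genomic-space intercellular heterogeneity statistic from 3D
    single-cell embeddings with standard QC and PCA contracts; and provides
    CUT&Tag peak analytics (per-chromosome mark density regression,
    poised/bivalent promoter calling, peak feature annotation, promoter
    log2 fold-change signal matrices with k-means clustering). A seeded
    synthetic-data generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
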