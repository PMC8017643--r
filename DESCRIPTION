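Package: txenrich
Title: Transcriptome-to-Enrichment Analysis for Shared Disease Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for detecting shared transcriptomic
    disease signatures across tissues and ages from bulk RNA-seq counts:
    low-count filtering, trimmed-mean-of-M-values (TMM) normalization,
    log2-counts-per-million, precision-weighted linear modelling with
    empirical-Bayes moderated t-statistics, Benjamini-Hochberg adjustment,
    signed -log(p) gene ranking, Jaccard-based gene-set redundancy filtering,
    ortholog mapping of gene-set collections, from-scratch pre-ranked gene set
    enrichment analysis (GSEA) with a gene-permutation null and sign-stratified
    FDR q values, cross-stratum shared-gene reporting, and qPCR delta-Ct
    validation with stability-based endogenous-control selection. Includes a
    negative-binomial synthetic-data generator with known ground truth so every
    stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
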