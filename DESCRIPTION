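Package: specdep
Title: Spectral-Count Differential Expression, Enrichment and Pathway Impact
    Analysis for Paired Cell-Line Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for label-free shotgun proteomics of a paired
    malignant/non-malignant cell-line model quantified by spectral counts.
    Provides ingestion and isoform consolidation of protein count tables,
    per-protein Wilcoxon rank-sum differential expression with
    Benjamini-Hochberg false discovery rate control and zero-safe log2 fold
    changes, hypergeometric overrepresentation analysis of protein classes
    with a resampling (random-subset) validation of enrichment calls,
    weighted running-sum gene set enrichment analysis with permutation
    significance and pooled-null FDR, topology-based signaling pathway
    impact analysis (perturbation accumulation over signed pathway graphs,
    bootstrap perturbation probability, combined global probability), and a
    race-stratified tumor/normal cohort comparison with race-specific
    non-malignant mean subtraction. A synthetic-data module generates
    overdispersed count matrices with nested replicates, annotation
    databases, random signed pathway topologies and two-race cohorts so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
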