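Package: gcimp
Title: Expression-Based Classification of the G-CIMP Methylation Subtype in Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to discover the glioma CpG island methylator phenotype
    (G-CIMP) from genome-wide DNA methylation beta values and to transfer that
    subtype call to mRNA expression cohorts. Provides k-means subtype discovery
    with Davies-Bouldin model selection, cross-platform batch-effect removal by
    per-feature additive ANOVA with normal-brain co-clustering validation, a
    five-model nearest-neighbour consensus classifier that abstains with
    Non-Consistent calls, per-gene Cox proportional-hazards survival screens
    with Benjamini-Hochberg correction, Gehan's generalized Wilcoxon test for
    censored survival, methylation-expression correlation summaries, and a
    synthetic multi-omics cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
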