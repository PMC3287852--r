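Package: pathenrich
Title: Pathway Enrichment Analysis Following Genetic Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-set (pathway) analysis downstream of a genetic association
    study on a mini-exome style dataset. Performs single-SNP additive linear
    regression for common variants and aggregate rare-allele burden regression
    per gene, with principal-component adjustment for population structure and
    genomic-control diagnostics; assigns each gene the p-value of its most
    significant genetic variable; and tests gene sets for enrichment by three
    methods sharing one phenotype-permutation engine: a weighted
    Kolmogorov-Smirnov enrichment score with permutation-normalized scores
    (GSEA), an empirical enrichment proportion test, and one-sided Fisher's
    exact overrepresentation of focus genes. Includes a synthetic
    multi-population mini-exome generator (Balding-Nichols divergence,
    rare-heavy allele-frequency spectrum, a causal pathway driving a
    quantitative trait, and a structured null trait) plus a replicate harness
    estimating power, type I error, and causal-pathway ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    vcfR,
    fgsea
Config/testthat/edition: 3
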