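#!/usr/bin/env Rscript
# Step 3 — pathway analysis of one replicate.
#
# Runs the full chain on replicate 1 of the heritable trait: association
# scan (common SNPs + rare-allele burdens, PC-adjusted), gene-level min-p
# scoring, then the three enrichment methods with a shared 200-permutation
# stream. Writes the three report tables and prints the top of each.

library(pathenrich)

seed <- 1
cfg <- sim_config()
bundle <- simulate_bundle(cfg, seed, n_replicates = 1)
an <- analyze_replicate(bundle$genotypes, bundle$genemap, bundle$gene_sets,
                        bundle$phenotypes[[1]], trait = "q1",
                        B = 200, seed = 42)

message(sprintf("lambda: %.3f unadjusted, %.3f PC-adjusted (PCs: %s)",
                an$lambda_unadjusted, an$lambda_adjusted,
                paste(an$selected_pcs, collapse = ",")))
message("\ntop genes by min-p:")
print(utils::head(as.data.frame(an$scores), 8), row.names = FALSE)

dir.create("results", showWarnings = FALSE)
ord <- function(d, p) d[order(d[[p]]), ]
utils::write.table(ord(an$gsea, "empirical_p"),
                   "results/enrichment_rep1_gsea.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ord(an$empirical, "empirical_p"),
                   "results/enrichment_rep1_empirical.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ord(an$fisher, "fisher_p"),
                   "results/enrichment_rep1_fisher.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("\nGSEA, top 3 sets by empirical p:")
print(utils::head(ord(an$gsea, "empirical_p"), 3), row.names = FALSE)
message("\nempirical enrichment, top 3:")
print(utils::head(ord(an$empirical, "empirical_p"), 3), row.names = FALSE)
message("\nFisher overrepresentation, top 3:")
print(utils::head(ord(an$fisher, "fisher_p"), 3), row.names = FALSE)
message("\nThe causal pathway should head the GSEA table: its dominant ",
        "gene carries most of the ranking weight, which the weighted ",
        "running-sum statistic rewards.")
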