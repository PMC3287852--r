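#!/usr/bin/env Rscript
# Step 1 — simulate the study system.
#
# Builds the default synthetic mini-exome bundle: 400 individuals from 4
# diverged subpopulations, 500 genes (~8 exonic variants each) with a
# rare-heavy allele-frequency spectrum, 100 gene sets including one causal
# pathway whose nine genes drive the heritable trait q1, and a structured
# null trait q4 whose mean differs between subpopulations. Writes the full
# bundle (VCF/GMT/TSV) under scratch/ and a compact data summary under
# results/.

library(pathenrich)

seed <- 1
cfg <- sim_config()
message("simulating 5 illustration replicates at seed ", seed, " ...")
bundle <- simulate_bundle(cfg, seed, n_replicates = 5)
write_bundle(bundle, "scratch/bundle")

g <- bundle$genotypes
sizes <- lengths(bundle$gene_sets)
summary_tab <- data.frame(
  quantity = c("n_samples", "n_populations", "n_genes", "n_variants",
               "maf_fraction_below_1pct", "maf_fraction_above_5pct",
               "n_common_variants", "n_gene_sets", "set_size_min",
               "set_size_median", "set_size_max", "causal_set_size"),
  value = c(length(g$sample_ids), nlevels(g$population),
            length(unique(bundle$genemap$gene)), length(g$variant_ids),
            round(mean(g$maf < 0.01), 3), round(mean(g$maf > 0.05), 3),
            sum(g$maf >= 0.01), length(sizes), min(sizes),
            stats::median(sizes), max(sizes),
            length(bundle$gene_sets[[cfg$causal_set_name]])))
dir.create("results", showWarnings = FALSE)
utils::write.table(summary_tab, "results/data_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

message("bundle written to scratch/bundle; summary:")
print(summary_tab, row.names = FALSE)
message("\nMore than half of the variants are rare (MAF < 1%) and about a ",
        "tenth are common above 5%, matching the mini-exome profile the ",
        "generator is designed to emulate.")
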