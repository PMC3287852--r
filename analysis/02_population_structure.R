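#!/usr/bin/env Rscript
# Step 2 — population structure and genomic control.
#
# Examines confounding of the two traits by subpopulation: ANOVA of each
# trait by population, then the genomic-control lambda of the common-SNP
# association scan on two replicates under three adjustments — none,
# population dummy variables, and the principal components selected per
# trait. The structured null trait q4 is strongly inflated without
# adjustment and corrected by the PCs.

library(pathenrich)

seed <- 1
cfg <- sim_config()
bundle <- simulate_bundle(cfg, seed, n_replicates = 2)
vars <- build_variables(bundle$genotypes, bundle$genemap)
pcs <- compute_pcs(bundle$genotypes)
Vc <- vars$V[, vars$meta$kind == "common_snp", drop = FALSE]

message("ANOVA of trait by population (replicate 1):")
ph1 <- bundle$phenotypes[[1]]
for (tr in c("q1", "q4")) {
  fit <- stats::aov(ph1[[tr]] ~ factor(ph1$population))
  s <- summary(fit)[[1]]
  message(sprintf("  %s: F = %.2f, df = %d, p = %.3g", tr,
                  s$`F value`[1], s$Df[1], s$`Pr(>F)`[1]))
}

rows <- list()
for (r in 1:2) {
  ph <- bundle$phenotypes[[r]]
  X0 <- as.matrix(ph[, c("Age", "Sex", "Smoking")])
  dummies <- stats::model.matrix(~ factor(ph$population))[, -1, drop = FALSE]
  for (tr in c("q1", "q4")) {
    sel <- select_pcs(pcs, ph[[tr]])
    Xpc <- if (length(sel)) cbind(X0, pcs$pcs[, sel, drop = FALSE]) else X0
    rows[[length(rows) + 1]] <- data.frame(
      trait = tr, replicate = r,
      selected_pcs = paste(sel, collapse = ","),
      lambda_none = genomic_lambda(association_scan(ph[[tr]], Vc, X0)$p_value),
      lambda_dummies = genomic_lambda(
        association_scan(ph[[tr]], Vc, cbind(X0, dummies))$p_value),
      lambda_pcs = genomic_lambda(association_scan(ph[[tr]], Vc, Xpc)$p_value))
  }
}
tab <- do.call(rbind, rows)
tab[, 4:6] <- round(tab[, 4:6], 3)
dir.create("results", showWarnings = FALSE)
utils::write.table(tab, "results/lambda_table.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("\nGenomic control (lambda) of the common-SNP scan:")
print(tab, row.names = FALSE)
message("\nThe null trait carries the population mean shifts, so its scan ",
        "is inflated (lambda ~2-3) until the selected PCs absorb the ",
        "structure; the heritable trait is not confounded here, so all its ",
        "lambdas sit near 1.")
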