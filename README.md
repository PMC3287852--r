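# pathenrich

Pathway (gene-set) enrichment analysis downstream of a genetic
association study, for quantitative traits on mini-exome style data.

Genome-wide association scans concentrate attention on the handful of
SNPs that clear a genome-wide threshold, discarding the information in
moderately associated variants. `pathenrich` asks whether the genes of a
pathway collectively rank higher in the association results than chance
allows. It implements the full chain for biostatisticians studying
rare-variant-rich exome data with population structure:

* **Association**: additive linear regression per common SNP
  (MAF ≥ 1%) and per-gene aggregate rare-allele burden regression
  (MAF < 1%), with Age/Sex/Smoking covariates, principal-component
  adjustment for population stratification, and genomic-control λ
  diagnostics.
* **Gene scores**: each gene gets the p-value of its most significant
  genetic variable, transformed to the ranking statistic
  r = Q<sub>χ²₁</sub>(1 − p<sub>min</sub>).
* **Three enrichment tests** sharing one phenotype-permutation engine:
  * *GSEA*: the weighted Kolmogorov–Smirnov running-sum enrichment score
    — walking the ranked gene list, the sum gains |r<sub>i</sub>|/N_R at
    set members and loses 1/(N − N_H) at non-members; ES(S) is the
    maximum of the sum. Permutations of the trait give the normalized
    score NES = (ES − mean ES<sub>π</sub>)/sd(ES<sub>π</sub>) and a
    one-sided empirical p-value.
  * *Empirical enrichment*: the proportion of member genes with
    gene-level p < 0.01, against the permutation null of the same
    proportion.
  * *Fisher overrepresentation*: one-sided hypergeometric test of
    focus genes (p<sub>min</sub> < 0.01) in the set versus the scored
    universe.
* **Synthetic study system**: a Balding–Nichols multi-population
  mini-exome generator (rare-heavy MAF spectrum, a 9-gene causal pathway
  driving a heritable trait, a structured null trait confounded with
  subpopulation) so the whole pipeline is testable without restricted
  data.
* **Evaluation harness**: power, per-replicate type I error (median
  summary), and the causal pathway's rank distribution across phenotype
  replicates.

## Worked example

```r
library(pathenrich)

cfg <- sim_config()                       # 400 samples, 500 genes, 100 sets
bundle <- simulate_bundle(cfg, seed = 1, n_replicates = 1)
an <- analyze_replicate(bundle$genotypes, bundle$genemap, bundle$gene_sets,
                        bundle$phenotypes[[1]], trait = "q1",
                        B = 200, seed = 42)
head(as.data.frame(an$scores), 3)
#>  gene        min_p best_variable_id         r rank
#>  G001 9.260644e-16          G001_c1 64.581808    1
#>  G002 2.086773e-07          G002_c1 26.951017    2
#>  G307 1.209717e-05      burden:G307 19.147882    3
an$gsea[order(an$gsea$empirical_p), ][1, ]
#>             set n_genes        es     nes empirical_p
#>  CAUSAL_PATHWAY      30 0.7015824 4.35641 0.004975124
```

The dominant causal gene (`G001`, planted common variant, p ≈ 1e-15)
heads the gene ranking; `burden:G307` shows a gene detected only through
its aggregate rare variants. The causal pathway tops the GSEA report at
the smallest attainable empirical p-value, 1/(B+1) ≈ 0.005.

The numbered drivers under `analysis/` run the full study and leave
compact tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R          # the synthetic mini-exome
Rscript analysis/02_population_structure.R   # ANOVA + lambda table
Rscript analysis/03_single_replicate_enrichment.R
Rscript analysis/04_power_type1.R            # 50-replicate evaluation (~3 min)
```

Step 4 prints, at the default study conditions:

```
  gsea       power = 1.000  median type I = 0.0100  rank 1-2 in 49
  empirical  power = 0.420  median type I = 0.0000  rank 1-2 in 41
  fisher     power = 0.440  median type I = 0.0000  rank 1-2 in 39
```

GSEA rides the dominant gene's weight in the running sum and detects the
causal pathway in every replicate at a calibrated type I error; the two
count-based tests are conservative (discrete statistics) and reach lower
power. The methods vignette
(`vignettes/pathway-enrichment-methods.Rmd`) explains the model, every
tunable parameter, and why the Fisher and empirical tests are
near-equivalent when they share one gene universe.

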