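#' Simulation configuration for the synthetic mini-exome
#'
#' Bundles every tunable of the generator. The defaults describe the
#' desk-scale study system: 400 unrelated individuals drawn from 4
#' diverged subpopulations, 500 genes carrying ~8 exonic variants each with
#' a rare-heavy allele-frequency spectrum (a little over half of variants
#' below 1% MAF, about a tenth above 5%), 100 gene sets of which one — the
#' causal pathway — contains the nine genes that drive the heritable
#' quantitative trait, and a second, structured null trait whose mean
#' differs between subpopulations but which is independent of every
#' genotype. A paper-scale profile (697 samples, 7 subpopulations, 3,205
#' genes, 601 sets, 200 replicates) is reachable through the arguments.
#'
#' @param n_samples total number of individuals.
#' @param pop_sizes integer vector of per-subpopulation sample sizes; must
#'   sum to `n_samples`.
#' @param fst per-subpopulation divergence from the ancestral population
#'   (Balding-Nichols F); length must match `pop_sizes`.
#' @param n_genes number of genes.
#' @param variants_per_gene_mean mean variants per gene (each gene draws
#'   `1 + Poisson(mean - 1)` variants, so the total is about
#'   `variants_per_gene_mean * n_genes`).
#' @param maf_frac_rare,maf_frac_common targets for the fraction of variants
#'   with folded MAF below 0.01 and above 0.05 respectively; their sum must
#'   not exceed 1.
#' @param n_gene_sets number of gene sets (the causal pathway included).
#' @param set_size_bounds inclusive `(min, max)` gene-set size bounds.
#' @param causal_set_name name given to the causal pathway.
#' @param causal_set_size size of the causal pathway (nine causal genes plus
#'   random members).
#' @param causal_effects data.frame with one row per causal gene: columns
#'   `gene` (symbol), `kind` (`"common"` or `"rare"`), `n_variants` (causal
#'   variants planted in the gene), `anc_freq` (ancestral allele frequency of
#'   each planted variant) and `beta` (trait effect per alternate allele).
#'   The default plants one dominant common-variant gene, four moderate
#'   common-variant genes and four rare-variant (burden-driven) genes, so
#'   that one gene reaches genome-wide significance while the others stay
#'   sub-threshold.
#' @param q4_pop_shift per-subpopulation mean offset of the null trait, in
#'   trait SD units; this is what makes the null trait confounded with
#'   population structure.
#' @param beta_age,beta_sex,beta_smoking covariate effects shared by both
#'   traits. Age and Sex are fixed across replicates; Smoking is redrawn per
#'   replicate.
#' @param noise_sd residual SD of both traits.
#' @param n_replicates default number of phenotype replicates per bundle.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 400,
                       pop_sizes = rep(n_samples / 4, 4),
                       fst = c(0.02, 0.06, 0.10, 0.15),
                       n_genes = 500,
                       variants_per_gene_mean = 8,
                       maf_frac_rare = 0.55,
                       maf_frac_common = 0.10,
                       n_gene_sets = 100,
                       set_size_bounds = c(10, 409),
                       causal_set_name = "CAUSAL_PATHWAY",
                       causal_set_size = 30,
                       causal_effects = default_causal_effects(),
                       q4_pop_shift = c(-0.65, -0.2, 0.2, 0.65),
                       beta_age = 0.01, beta_sex = 0.3, beta_smoking = 0.4,
                       noise_sd = 1,
                       n_replicates = 200) {
  pop_sizes <- as.integer(round(pop_sizes))
  cfg <- list(n_samples = as.integer(n_samples), pop_sizes = pop_sizes,
              fst = fst, n_genes = as.integer(n_genes),
              variants_per_gene_mean = variants_per_gene_mean,
              maf_frac_rare = maf_frac_rare, maf_frac_common = maf_frac_common,
              n_gene_sets = as.integer(n_gene_sets),
              set_size_bounds = as.integer(set_size_bounds),
              causal_set_name = causal_set_name,
              causal_set_size = as.integer(causal_set_size),
              causal_effects = causal_effects,
              q4_pop_shift = q4_pop_shift,
              beta_age = beta_age, beta_sex = beta_sex,
              beta_smoking = beta_smoking,
              noise_sd = noise_sd, n_replicates = as.integer(n_replicates))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default causal-gene effect model
#'
#' Nine causal genes in one pathway: `G001` carries a single common variant
#' with a large effect (the dominant gene), `G002`-`G005` carry common
#' variants with moderate-to-weak effects, and `G006`-`G009` carry several
#' rare variants whose signal is only visible to the aggregate rare-allele
#' burden test.
#'
#' @return data.frame with columns `gene`, `kind`, `n_variants`, `anc_freq`,
#'   `beta`.
#' @export
default_causal_effects <- function() {
  data.frame(
    gene = sprintf("G%03d", 1:9),
    kind = c("common", "common", "common", "common", "common",
             "rare", "rare", "rare", "rare"),
    n_variants = c(1L, 1L, 1L, 1L, 1L, 4L, 4L, 4L, 4L),
    anc_freq = c(0.20, 0.08, 0.08, 0.08, 0.08, 0.004, 0.004, 0.004, 0.004),
    beta = c(0.80, 0.55, 0.55, 0.55, 0.55, 1.30, 1.30, 0.90, 0.90),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  if (sum(cfg$pop_sizes) != cfg$n_samples)
    stop("pop_sizes must sum to n_samples")
  if (length(cfg$fst) != length(cfg$pop_sizes))
    stop("fst must have one entry per subpopulation")
  if (any(cfg$fst < 0 | cfg$fst >= 1)) stop("fst values must be in [0, 1)")
  if (cfg$maf_frac_rare < 0 || cfg$maf_frac_common < 0 ||
      cfg$maf_frac_rare + cfg$maf_frac_common > 1)
    stop("infeasible MAF spectrum: band fractions must be nonnegative and sum to <= 1")
  if (length(cfg$q4_pop_shift) != length(cfg$pop_sizes))
    stop("q4_pop_shift must have one entry per subpopulation")
  if (cfg$set_size_bounds[1] > cfg$set_size_bounds[2])
    stop("set_size_bounds must be nondecreasing")
  if (cfg$causal_set_size > cfg$n_genes || cfg$set_size_bounds[1] > cfg$n_genes)
    stop("gene-set size bounds infeasible for n_genes")
  if (cfg$causal_set_size < nrow(cfg$causal_effects))
    stop("causal_set_size smaller than the number of causal genes")
  if (!all(cfg$causal_effects$kind %in% c("common", "rare")))
    stop("causal_effects$kind must be 'common' or 'rare'")
  invisible(cfg)
}

# Deterministic per-component seed streams derived from one master seed.
# Streams are numbered so that individual replicates are reproducible on
# their own; all results stay below 2^31 - 1.
.stream_seed <- function(master, stream_id) {
  (as.numeric(master) * 48271 + as.numeric(stream_id)) %% 2147483647
}
.STREAMS <- c(genotypes = 1, gene_sets = 2, covariates_fixed = 3)
.replicate_stream <- function(replicate_index) 1000 + replicate_index
.permutation_stream <- function(replicate_index) 500000 + replicate_index

# Draw ancestral allele frequencies from a three-band log-uniform mixture
# aimed at the configured rare / intermediate / common REALIZED fractions.
# Band edges and the down-weighting of the common band compensate for the
# Balding-Nichols divergence and finite-sample binomial noise, which smear
# intermediate ancestral frequencies across the 1% and 5% folded-MAF
# boundaries (calibrated by Monte Carlo against the targets).
.draw_ancestral_freq <- function(n, cfg) {
  w_common <- cfg$maf_frac_common / 2
  w <- c(cfg$maf_frac_rare, 1 - cfg$maf_frac_rare - w_common, w_common)
  band <- sample.int(3, n, replace = TRUE, prob = w)
  lo <- c(1.5e-3, 0.020, 0.10)[band]
  hi <- c(0.011, 0.035, 0.35)[band]
  exp(stats::runif(n, log(lo), log(hi)))
}

# Balding-Nichols subpopulation frequency given ancestral p and divergence F
.bn_freq <- function(p, f) {
  if (f <= 0) return(rep(p, length.out = max(length(p), 1L)))
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  stats::rbeta(length(p), a, b)
}

#' Simulate structured mini-exome genotypes
#'
#' Draws a genotype matrix under a Balding-Nichols model: each variant has
#' an ancestral allele frequency from the configured rare-heavy spectrum;
#' each subpopulation draws its own frequency from a Beta distribution
#' centred on the ancestral value with divergence `fst`; individual dosages
#' are Binomial(2, subpopulation frequency). Causal variants declared in
#' `config$causal_effects` are planted in their genes with the configured
#' ancestral frequencies and identifiable variant ids
#' (`<gene>_c<k>`).
#'
#' @param config a [sim_config()].
#' @param seed master seed; the genotype stream is derived from it, so the
#'   same config + seed always yields the identical matrix.
#' @return list with elements `genotypes` (a [genotype_matrix()] with
#'   population labels), `genemap` (variant -> gene data.frame) and
#'   `causal_variants` (data.frame `variant_id`, `gene`, `beta`).
#' @export
simulate_genotypes <- function(config, seed) {
  validate_sim_config(config)
  set.seed(.stream_seed(seed, .STREAMS["genotypes"]))
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  n_var <- 1L + stats::rpois(config$n_genes,
                             max(config$variants_per_gene_mean - 1, 0))
  ce <- config$causal_effects
  if (!all(ce$gene %in% genes)) stop("causal genes outside the gene universe")

  variant_ids <- character(0)
  gene_of <- character(0)
  anc <- numeric(0)
  causal_rows <- list()
  for (i in seq_len(config$n_genes)) {
    gsym <- genes[i]
    ids <- sprintf("%s_v%d", gsym, seq_len(n_var[i]))
    p <- .draw_ancestral_freq(n_var[i], config)
    j <- match(gsym, ce$gene)
    if (!is.na(j)) {
      cv_ids <- sprintf("%s_c%d", gsym, seq_len(ce$n_variants[j]))
      ids <- c(cv_ids, ids)
      p <- c(rep(ce$anc_freq[j], ce$n_variants[j]), p)
      causal_rows[[gsym]] <- data.frame(variant_id = cv_ids, gene = gsym,
                                        beta = ce$beta[j],
                                        stringsAsFactors = FALSE)
    }
    variant_ids <- c(variant_ids, ids)
    gene_of <- c(gene_of, rep(gsym, length(ids)))
    anc <- c(anc, p)
  }

  m <- length(variant_ids)
  n_pop <- length(config$pop_sizes)
  pop_label <- rep(sprintf("POP%d", seq_len(n_pop)), config$pop_sizes)
  dos <- matrix(0L, nrow = config$n_samples, ncol = m)
  row0 <- 0L
  for (k in seq_len(n_pop)) {
    nk <- config$pop_sizes[k]
    pk <- .bn_freq(anc, config$fst[k])
    pk <- pmin(pmax(pk, 0), 1)
    dos[row0 + seq_len(nk), ] <- matrix(
      stats::rbinom(nk * m, 2L, rep(pk, each = nk)), nrow = nk)
    row0 <- row0 + nk
  }
  g <- genotype_matrix(dos,
                       sample_ids = sprintf("S%04d", seq_len(config$n_samples)),
                       variant_ids = variant_ids,
                       population = pop_label)
  genemap <- data.frame(variant_id = variant_ids, gene = gene_of,
                        stringsAsFactors = FALSE)
  causal <- do.call(rbind, causal_rows)
  rownames(causal) <- NULL
  list(genotypes = g, genemap = genemap, causal_variants = causal)
}

#' Simulate a gene-set collection containing one causal pathway
#'
#' The first set is the causal pathway: the nine causal genes plus random
#' members up to `causal_set_size`. The remaining `n_gene_sets - 1` sets
#' draw their sizes from a log-normal (median ~40 genes) truncated to the
#' configured bounds and their members uniformly from the gene universe, so
#' genes can belong to several sets.
#'
#' @param config a [sim_config()].
#' @param genemap gene map from [simulate_genotypes()] (defines the gene
#'   universe and its order).
#' @param seed master seed (gene-set stream derived from it).
#' @return a [gene_set_collection()].
#' @export
simulate_gene_sets <- function(config, genemap, seed) {
  validate_sim_config(config)
  set.seed(.stream_seed(seed, .STREAMS["gene_sets"]))
  genes <- unique(genemap$gene)
  ce_genes <- config$causal_effects$gene
  filler <- sample(setdiff(genes, ce_genes),
                   config$causal_set_size - length(ce_genes))
  sets <- list(sample(c(ce_genes, filler)))  # shuffled member order
  names(sets) <- config$causal_set_name
  desc <- "causal pathway (drives the heritable trait)"
  if (config$n_gene_sets > 1L) {
    lo <- config$set_size_bounds[1]
    hi <- min(config$set_size_bounds[2], length(genes))
    sizes <- pmin(pmax(round(stats::rlnorm(config$n_gene_sets - 1L,
                                           log(40), 0.7)), lo), hi)
    for (i in seq_len(config$n_gene_sets - 1L)) {
      sets[[sprintf("SET%03d", i)]] <- sample(genes, sizes[i])
      desc <- c(desc, "random gene set")
    }
  }
  gene_set_collection(sets, desc)
}

#' Simulate one replicate of the two quantitative traits
#'
#' Builds the covariates and two traits for one replicate:
#' * `q1` (heritable): covariate effects + the sum of `beta * dosage` over
#'   the planted causal variants + Gaussian noise;
#' * `q4` (structured null): covariate effects + a per-subpopulation mean
#'   shift + Gaussian noise — independent of every genotype given the
#'   population label, so any association with it is a false positive.
#'
#' Age and Sex are drawn once from the master seed and are identical across
#' replicates; Smoking and the noise are redrawn per replicate.
#'
#' @param genotypes a [genotype_matrix()] with population labels.
#' @param genemap its gene map (unused directly; kept for interface
#'   symmetry and validation).
#' @param config a [sim_config()].
#' @param replicate_index 1-based replicate number.
#' @param seed master seed.
#' @param causal_variants data.frame (`variant_id`, `gene`, `beta`) from
#'   [simulate_genotypes()].
#' @return data.frame: `sample_id`, `population`, `Age`, `Sex`, `Smoking`,
#'   `q1`, `q4`.
#' @export
simulate_traits <- function(genotypes, genemap, config, replicate_index, seed,
                            causal_variants) {
  validate_sim_config(config)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!is.null(causal_variants) &&
      !all(causal_variants$variant_id %in% genotypes$variant_ids))
    stop("causal variants absent from the genotype matrix")
  n <- length(genotypes$sample_ids)

  set.seed(.stream_seed(seed, .STREAMS["covariates_fixed"]))
  age <- stats::rnorm(n, 50, 10)
  sex <- stats::rbinom(n, 1L, 0.5)

  set.seed(.stream_seed(seed, .replicate_stream(replicate_index)))
  smoking <- stats::rbinom(n, 1L, 0.3)
  covar_part <- config$beta_age * age + config$beta_sex * sex +
    config$beta_smoking * smoking

  genetic <- numeric(n)
  if (!is.null(causal_variants) && nrow(causal_variants) > 0L) {
    idx <- match(causal_variants$variant_id, genotypes$variant_ids)
    genetic <- as.numeric(genotypes$dosages[, idx, drop = FALSE] %*%
                            causal_variants$beta)
  }
  q1 <- covar_part + genetic + stats::rnorm(n, 0, config$noise_sd)

  pop_idx <- as.integer(genotypes$population)
  q4 <- covar_part + config$q4_pop_shift[pop_idx] +
    stats::rnorm(n, 0, config$noise_sd)

  data.frame(sample_id = genotypes$sample_ids,
             population = as.character(genotypes$population),
             Age = age, Sex = sex, Smoking = smoking,
             q1 = q1, q4 = q4, stringsAsFactors = FALSE)
}

#' Simulate a full replicate bundle
#'
#' One call produces everything the downstream pipeline needs: genotypes
#' and gene map (fixed across replicates), the gene-set collection (fixed),
#' and `n_replicates` phenotype tables (each with the heritable trait `q1`
#' and the structured null trait `q4`).
#'
#' @param config a [sim_config()].
#' @param seed master seed; replicate seeds are derived from it by a
#'   counter-based scheme so each replicate is individually reproducible.
#' @param n_replicates number of phenotype replicates (defaults to
#'   `config$n_replicates`).
#' @return list of class `replicate_bundle` with elements `genotypes`,
#'   `genemap`, `gene_sets`, `causal_variants`, `phenotypes` (list of
#'   data.frames), `config`, `seed`.
#' @export
simulate_bundle <- function(config, seed, n_replicates = config$n_replicates) {
  sim <- simulate_genotypes(config, seed)
  gene_sets <- simulate_gene_sets(config, sim$genemap, seed)
  phen <- lapply(seq_len(n_replicates), function(r) {
    simulate_traits(sim$genotypes, sim$genemap, config, r, seed,
                    sim$causal_variants)
  })
  structure(list(genotypes = sim$genotypes, genemap = sim$genemap,
                 gene_sets = gene_sets, causal_variants = sim$causal_variants,
                 phenotypes = phen, config = config, seed = seed),
            class = "replicate_bundle")
}

#' Write a replicate bundle to a directory
#'
#' Emits the standard formats: `genotypes.vcf`, `genemap.tsv`, `sets.gmt`,
#' `causal_variants.tsv`, one `pheno_rep<k>.tsv` per replicate, and a
#' `manifest.json` recording the configuration, master seed and package
#' version, from which the bundle can be regenerated bit-identically.
#'
#' @param bundle a `replicate_bundle` from [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "replicate_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(bundle$genotypes, file.path(dir, "genotypes.vcf"))
  prov <- c(sprintf("pathenrich %s",
                    as.character(utils::packageVersion("pathenrich"))),
            sprintf("seed %s", format(bundle$seed)))
  write_genemap(bundle$genemap, file.path(dir, "genemap.tsv"), comment = prov)
  write_gmt(bundle$gene_sets, file.path(dir, "sets.gmt"))
  utils::write.table(bundle$causal_variants,
                     file.path(dir, "causal_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # population label travels with the phenotype tables
  for (r in seq_along(bundle$phenotypes)) {
    write_phenotypes(bundle$phenotypes[[r]],
                     file.path(dir, sprintf("pheno_rep%03d.tsv", r)),
                     comment = c(prov, sprintf("replicate %d", r)))
  }
  cfg <- unclass(bundle$config)
  jsonlite::write_json(
    list(config = cfg, seed = bundle$seed,
         n_replicates = length(bundle$phenotypes),
         version = as.character(utils::packageVersion("pathenrich"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a replicate bundle back from a directory
#'
#' @param dir directory written by [write_bundle()].
#' @return a `replicate_bundle` equal (on ids, dosages, sets and trait
#'   values to write/read precision) to the one written.
#' @export
read_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- man$config
  cfg$causal_effects <- as.data.frame(cfg$causal_effects)
  class(cfg) <- "sim_config"
  g <- read_vcf(file.path(dir, "genotypes.vcf"))
  genemap <- read_genemap(file.path(dir, "genemap.tsv"))
  gene_sets <- read_gmt(file.path(dir, "sets.gmt"))
  causal <- utils::read.table(file.path(dir, "causal_variants.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  phen_files <- sort(list.files(dir, pattern = "^pheno_rep[0-9]+\\.tsv$",
                                full.names = TRUE))
  phen <- lapply(phen_files, read_phenotypes)
  g$population <- factor(phen[[1]]$population[match(g$sample_ids,
                                                    phen[[1]]$sample_id)])
  structure(list(genotypes = g, genemap = genemap, gene_sets = gene_sets,
                 causal_variants = causal, phenotypes = phen,
                 config = cfg, seed = man$seed),
            class = "replicate_bundle")
}
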