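#' Full pathway analysis of one phenotype replicate
#'
#' Runs the complete per-replicate chain: build the genetic variables
#' (common-SNP dosages + per-gene rare burden counts), select the PCs
#' marginally associated with the trait, scan with Age/Sex/Smoking + the
#' selected PCs as covariates, score genes by min-p, and apply the three
#' enrichment methods (GSEA with permutation-normalized scores, empirical
#' enrichment, Fisher overrepresentation) sharing one permutation stream.
#' Genomic-control lambda is reported for the common-SNP tests both without
#' and with the PC adjustment.
#'
#' @param genotypes a [genotype_matrix()].
#' @param genemap variant-to-gene map.
#' @param gene_sets a [gene_set_collection()].
#' @param pheno phenotype data.frame (must contain `trait` and the
#'   `covariates` columns, aligned with the genotype samples).
#' @param trait name of the trait column.
#' @param covariates names of the covariate columns (default Age, Sex,
#'   Smoking).
#' @param pcs optional precomputed [compute_pcs()] result (computed here
#'   when `NULL`).
#' @param pc_alpha marginal-selection level for PCs (default 0.05).
#' @param B number of phenotype permutations (default 1000).
#' @param seed permutation-stream seed.
#' @param alpha_gene gene-level threshold for the proportion statistic and
#'   the focus genes (default 0.01).
#' @param weight_exponent ES weight exponent (default 1).
#' @param size_bounds gene-set size bounds after restriction.
#' @param maf_threshold common/rare MAF boundary (default 0.01).
#' @param variables optional precomputed [build_variables()] result (saves
#'   recomputation across replicates of one bundle).
#' @return list of class `replicate_analysis`: `gsea`, `empirical`,
#'   `fisher` (result tables), `scores`, `selected_pcs`,
#'   `lambda_unadjusted`, `lambda_adjusted`, `null` (the
#'   `permutation_null`).
#' @export
analyze_replicate <- function(genotypes, genemap, gene_sets, pheno, trait,
                              covariates = c("Age", "Sex", "Smoking"),
                              pcs = NULL, pc_alpha = 0.05,
                              B = 1000, seed = 1,
                              alpha_gene = 0.01, weight_exponent = 1,
                              size_bounds = c(10, 409), maf_threshold = 0.01,
                              variables = NULL) {
  stopifnot(trait %in% names(pheno), all(covariates %in% names(pheno)))
  if (!identical(as.character(pheno$sample_id), genotypes$sample_ids))
    stop("phenotype rows must align one-to-one with the genotype samples")
  y <- pheno[[trait]]
  if (stats::var(y) <= 0) stop("trait has zero variance")
  X0 <- as.matrix(pheno[, covariates, drop = FALSE])
  if (is.null(variables))
    variables <- build_variables(genotypes, genemap, maf_threshold)
  if (is.null(pcs)) pcs <- compute_pcs(genotypes, maf_threshold)
  sel <- select_pcs(pcs, y, pc_alpha)
  X <- if (length(sel) > 0) cbind(X0, pcs$pcs[, sel, drop = FALSE]) else X0

  common_cols <- variables$meta$kind == "common_snp"
  p_unadj <- association_scan(y, variables$V[, common_cols, drop = FALSE],
                              X0)$p_value
  p_adj <- association_scan(y, variables$V[, common_cols, drop = FALSE],
                            X)$p_value
  lam_unadj <- genomic_lambda(p_unadj)
  lam_adj <- genomic_lambda(p_adj)

  null <- permute_and_rescore(y, variables$V, variables$meta, X, gene_sets,
                              B = B, seed = seed,
                              weight_exponent = weight_exponent,
                              alpha_gene = alpha_gene,
                              size_bounds = size_bounds)
  structure(list(gsea = normalize_and_test(null),
                 empirical = empirical_enrichment(null),
                 fisher = fisher_overrepresentation(null$scores, gene_sets,
                                                    focus_alpha = alpha_gene,
                                                    size_bounds = size_bounds),
                 scores = null$scores, selected_pcs = sel,
                 lambda_unadjusted = lam_unadj, lambda_adjusted = lam_adj,
                 null = null),
            class = "replicate_analysis")
}

# deterministic ordering of sets by method p-value with the method's
# tie-breaker (larger statistic first, then set name)
.rank_sets <- function(result, method) {
  switch(method,
    gsea = order(result$empirical_p, -result$nes, result$set),
    empirical = order(result$empirical_p, -result$proportion, result$set),
    fisher = order(result$fisher_p, -result$overlap, result$set),
    stop("unknown method: ", method))
}

.method_p <- function(result, method) {
  switch(method, gsea = result$empirical_p,
         empirical = result$empirical_p, fisher = result$fisher_p)
}

#' Per-replicate outcome rows for one analyzed replicate
#'
#' Condenses a [analyze_replicate()] result into one row per method:
#' the causal set's p-value and rank (1 = most significant, ties broken by
#' the method statistic then set name), the number of significant sets at
#' `alpha`, and the number of sets analyzed.
#'
#' @param analysis a `replicate_analysis`.
#' @param causal_set name of the designated causal pathway.
#' @param alpha set-level significance threshold (default 0.01).
#' @param replicate_index replicate number recorded in the rows.
#' @return data.frame: `replicate`, `method`, `causal_p`, `causal_rank`,
#'   `causal_significant`, `n_significant`, `n_sets`, `lambda_unadjusted`,
#'   `lambda_adjusted`.
#' @export
replicate_outcomes <- function(analysis, causal_set, alpha = 0.01,
                               replicate_index = NA_integer_) {
  rows <- lapply(c("gsea", "empirical", "fisher"), function(m) {
    res <- analysis[[m]]
    pv <- .method_p(res, m)
    ord <- .rank_sets(res, m)
    ci <- match(causal_set, res$set)
    data.frame(replicate = replicate_index, method = m,
               causal_p = if (is.na(ci)) NA_real_ else pv[ci],
               causal_rank = if (is.na(ci)) NA_integer_ else match(ci, ord),
               causal_significant = if (is.na(ci)) NA else pv[ci] < alpha,
               n_significant = sum(pv < alpha, na.rm = TRUE),
               n_sets = nrow(res),
               lambda_unadjusted = analysis$lambda_unadjusted,
               lambda_adjusted = analysis$lambda_adjusted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Power estimate over replicates
#'
#' The proportion of replicates in which a method calls the causal pathway
#' significantly enriched at `alpha`.
#'
#' @param outcomes stacked [replicate_outcomes()] rows from the
#'   causal-trait analyses.
#' @param alpha set-level threshold (default 0.01; applied to the stored
#'   causal p-values, so power is monotone non-decreasing in `alpha`).
#' @return named numeric vector, one power estimate per method.
#' @export
power_estimate <- function(outcomes, alpha = 0.01) {
  if (anyNA(outcomes$causal_p))
    stop("causal set missing from analyzed sets in replicate(s): ",
         paste(unique(outcomes$replicate[is.na(outcomes$causal_p)]),
               collapse = ", "))
  tapply(outcomes$causal_p < alpha, outcomes$method, mean)[
    unique(outcomes$method)]
}

#' Per-replicate type I error and its median
#'
#' On null-trait outcomes, each replicate's type I error is the proportion
#' of analyzed gene sets called significant at `alpha`; the summary is the
#' median across replicates.
#'
#' @param outcomes stacked [replicate_outcomes()] rows from null-trait
#'   analyses.
#' @return list per method: `per_replicate` (numeric vector) and `median`.
#' @export
type1_estimate <- function(outcomes) {
  if (any(outcomes$n_sets == 0)) stop("replicate with zero analyzed sets")
  res <- lapply(split(outcomes, outcomes$method), function(d) {
    v <- d$n_significant / d$n_sets
    list(per_replicate = v, median = stats::median(v))
  })
  res[unique(outcomes$method)]
}

#' Histogram of the causal pathway's rank across replicates
#'
#' @param ranks integer vector of causal-set ranks (1 = most significant).
#' @param breaks upper edges of the rank bins; the default bins are
#'   1-2, 3-5, 6-10, 11+.
#' @return named integer vector of counts (sums to `length(ranks)`).
#' @export
rank_histogram <- function(ranks, breaks = c(2, 5, 10, Inf)) {
  lo <- c(1, utils::head(breaks, -1) + 1)
  labels <- ifelse(is.finite(breaks), paste0(lo, "-", breaks),
                   paste0(lo, "+"))
  labels[lo == breaks] <- as.character(lo[lo == breaks])
  bin <- findInterval(ranks, c(lo, Inf), left.open = FALSE)
  counts <- tabulate(bin, nbins = length(breaks))
  names(counts) <- labels
  counts
}

#' Run the full replicate evaluation experiment
#'
#' Simulates (or resumes) a replicate bundle and, for every replicate, runs
#' the full association -> gene-scoring -> three-method enrichment chain on
#' the heritable trait (power) and on the structured null trait (type I
#' error), persisting one outcome file per replicate and trait so a rerun
#' of a completed directory is a no-op. Produces the evaluation summary:
#' per-method power, per-replicate type I error and its median, and the
#' causal pathway's rank histogram.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param seed master seed (drives the bundle and all permutation streams).
#' @param n_replicates replicates to evaluate (default 50).
#' @param B permutations per replicate (default 200).
#' @param alpha set-level significance threshold (default 0.01).
#' @param power_trait,null_trait phenotype column names bound explicitly to
#'   the power and type-I analyses.
#' @param verbose print per-replicate progress.
#' @return list of class `evaluation_summary`: per method `power`,
#'   `type1_median`, `type1_per_replicate`, `rank_counts`; plus
#'   `lambda` (per-replicate unadjusted/adjusted lambdas on the null
#'   trait), `n_replicates`, `B`, `alpha`, `seed`. Also written to
#'   `out_dir/summary.json` and TSV companions.
#' @export
run_experiment <- function(config, out_dir, seed = 1, n_replicates = 50,
                           B = 200, alpha = 0.01,
                           power_trait = "q1", null_trait = "q4",
                           verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                            digits = NA))
  man_path <- file.path(out_dir, "experiment_manifest.json")
  if (file.exists(man_path)) {
    old <- jsonlite::read_json(man_path, simplifyVector = FALSE)
    if (!identical(old$config_json, cfg_json) ||
        !identical(as.numeric(old$seed), as.numeric(seed)))
      stop("out_dir holds an experiment with a different config/seed; ",
           "refusing to mix results")
  } else {
    jsonlite::write_json(list(config_json = cfg_json, seed = seed,
                              n_replicates = n_replicates, B = B),
                         man_path, auto_unbox = TRUE, digits = NA)
  }

  bundle <- simulate_bundle(config, seed, n_replicates)
  variables <- build_variables(bundle$genotypes, bundle$genemap)
  pcs <- compute_pcs(bundle$genotypes)
  causal <- config$causal_set_name

  run_trait <- function(trait, stream_offset) {
    rows <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      f <- file.path(out_dir, sprintf("outcomes_%s_rep%03d.tsv", trait, r))
      if (file.exists(f)) {
        rows[[r]] <- utils::read.table(f, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
        next
      }
      an <- analyze_replicate(bundle$genotypes, bundle$genemap,
                              bundle$gene_sets, bundle$phenotypes[[r]],
                              trait = trait, pcs = pcs, B = B,
                              seed = .stream_seed(seed, stream_offset + r),
                              variables = variables)
      out <- replicate_outcomes(an, causal, alpha, replicate_index = r)
      utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
      rows[[r]] <- out
      if (verbose) message(sprintf("%s replicate %d/%d done", trait, r,
                                   n_replicates))
    }
    do.call(rbind, rows)
  }
  power_out <- run_trait(power_trait, 500000)
  null_out <- run_trait(null_trait, 700000)

  pw <- power_estimate(power_out, alpha)
  t1 <- type1_estimate(null_out)
  methods <- unique(power_out$method)
  summary <- list()
  for (m in methods) {
    ranks <- power_out$causal_rank[power_out$method == m]
    summary[[m]] <- list(power = unname(pw[m]),
                         type1_median = t1[[m]]$median,
                         type1_per_replicate = t1[[m]]$per_replicate,
                         rank_counts = as.list(rank_histogram(ranks)))
  }
  lam <- unique(null_out[, c("replicate", "lambda_unadjusted",
                             "lambda_adjusted")])
  out <- structure(c(summary,
                     list(lambda = lam, n_replicates = n_replicates, B = B,
                          alpha = alpha, seed = seed)),
                   class = "evaluation_summary")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  hist_tab <- do.call(rbind, lapply(methods, function(m) {
    data.frame(method = m, bin = names(summary[[m]]$rank_counts),
               count = unlist(summary[[m]]$rank_counts),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(hist_tab, file.path(out_dir, "rank_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lam, file.path(out_dir, "lambda.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("evaluation over %d replicates (B = %d, alpha = %g)\n",
              x$n_replicates, x$B, x$alpha))
  for (m in setdiff(names(x), c("lambda", "n_replicates", "B", "alpha",
                                "seed"))) {
    cat(sprintf("  %-10s power = %.3f  median type I = %.4f  rank 1-2 in %s\n",
                m, x[[m]]$power, x[[m]]$type1_median,
                x[[m]]$rank_counts[[1]]))
  }
  invisible(x)
}
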